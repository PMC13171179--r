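#' Allometric log-ratio correction
#'
#' Removes the body-size axis from linear measurements before graph
#' construction. Each morphometric trait `t` other than total length becomes
#' the log shape ratio `ln(t / TL)`; total length itself is kept as `ln(TL)`
#' so a single size axis remains in the feature set; meristic counts `x`
#' become `ln(x + 1)` to homogenise their variances.
#'
#' @param table a [trait_table()].
#' @return numeric N x P matrix of corrected (unstandardised) values, with
#'   column names in trait order and an attribute `correction_log` recording
#'   the transform applied per trait.
#' @export
allometric_correct <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  tl <- table$data[[table$tl_name]]
  if (any(tl <= 0)) stop("total length must be strictly positive", call. = FALSE)
  traits <- names(table$trait_kinds)
  out <- matrix(NA_real_, nrow = length(tl), ncol = length(traits),
                dimnames = list(table$specimen_id, traits))
  log_rec <- character(length(traits))
  names(log_rec) <- traits
  for (tr in traits) {
    v <- table$data[[tr]]
    kind <- table$trait_kinds[[tr]]
    if (kind == "morphometric") {
      if (any(v <= 0)) {
        stop("morphometric trait '", tr, "' must be > 0 for the log ratio",
             call. = FALSE)
      }
      if (tr == table$tl_name) {
        out[, tr] <- log(v)
        log_rec[tr] <- "log(TL)"
      } else {
        out[, tr] <- log(v / tl)
        log_rec[tr] <- "log(trait/TL)"
      }
    } else {
      if (any(v < 0)) stop("meristic trait '", tr, "' is negative", call. = FALSE)
      out[, tr] <- log1p(v)
      log_rec[tr] <- "log(x+1)"
    }
  }
  attr(out, "correction_log") <- log_rec
  out
}

#' Standardise a corrected trait matrix
#'
#' Centres every column to mean 0 and scales it to unit sample variance
#' (denominator N - 1). Constant columns cannot be scaled: by default this is
#' an error; with `drop_constant = TRUE` they are removed with a warning.
#'
#' @param x numeric matrix with no non-finite entries.
#' @param drop_constant drop zero-variance columns instead of failing.
#' @return a `corrected_matrix`: the standardised matrix with attributes
#'   `trait_names`, `correction_log` (carried over if present) and
#'   `dropped` (names of removed constant columns).
#' @export
standardize_traits <- function(x, drop_constant = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("non-finite entries in trait matrix", call. = FALSE)
  corr_log <- attr(x, "correction_log")
  sds <- apply(x, 2L, stats::sd)
  dropped <- character(0)
  if (any(sds == 0)) {
    const <- colnames(x)[sds == 0]
    if (!drop_constant) {
      stop("zero-variance column(s): ", paste(const, collapse = ", "),
           "; use drop_constant = TRUE to remove them", call. = FALSE)
    }
    warning("dropping constant column(s): ", paste(const, collapse = ", "),
            call. = FALSE)
    dropped <- const
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(x, center = TRUE, scale = sds)
  out <- matrix(as.numeric(z), nrow = nrow(x), ncol = ncol(x),
                dimnames = dimnames(x))
  structure(out,
            trait_names = colnames(out),
            correction_log = corr_log,
            dropped = dropped,
            class = c("corrected_matrix", "matrix", "array"))
}

#' Preprocess a trait table into the analysis feature matrix
#'
#' Convenience wrapper: [allometric_correct()] followed by
#' [standardize_traits()]. The result is the N x P feature matrix every
#' downstream stage (k-NN graph, autoencoder, PCA baseline) operates on.
#'
#' @inheritParams allometric_correct
#' @inheritParams standardize_traits
#' @return a `corrected_matrix` (see [standardize_traits()]).
#' @export
preprocess_traits <- function(table, drop_constant = FALSE) {
  standardize_traits(allometric_correct(table), drop_constant = drop_constant)
}

#' Write a corrected matrix to CSV for audit
#'
#' @param x a `corrected_matrix`.
#' @param path output CSV path; first column is the specimen id.
#' @export
write_corrected_matrix <- function(x, path) {
  df <- data.frame(specimen_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
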