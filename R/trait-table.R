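#' Construct and validate a specimen-by-trait table
#'
#' A `trait_table` holds raw measurements for a set of specimens: continuous
#' morphometric traits (linear measurements in mm, including the designated
#' total-length trait used as the allometric size denominator) and meristic
#' traits (integer scale counts, "pholidosis" in the squamate literature).
#' Every trait must be declared as either `"morphometric"` or `"meristic"`;
#' validation enforces the admissibility rules the downstream log transforms
#' require (strictly positive lengths, non-negative integer counts).
#'
#' @param data data.frame with one row per specimen.
#' @param trait_kinds named character vector mapping each trait column to
#'   `"morphometric"` or `"meristic"`. Defines the trait set and its order.
#' @param tl_name name of the total-length column (must be morphometric).
#' @param id_col name of the specimen-id column. Ids must be unique.
#' @param species_col optional name of a species-label column, or `NULL`.
#'
#' @return An object of class `trait_table`: a list with `data` (traits only,
#'   numeric), `specimen_id`, `species`, `trait_kinds`, `tl_name`.
#' @export
trait_table <- function(data, trait_kinds, tl_name, id_col = "specimen_id",
                        species_col = NULL) {
  stopifnot(is.data.frame(data))
  traits <- names(trait_kinds)
  if (length(traits) < 2L || nrow(data) < 2L) {
    stop("a trait table needs at least 2 specimens and 2 traits", call. = FALSE)
  }
  if (!all(trait_kinds %in% c("morphometric", "meristic"))) {
    stop("trait kinds must be 'morphometric' or 'meristic'", call. = FALSE)
  }
  missing_cols <- setdiff(c(id_col, traits, species_col), names(data))
  if (length(missing_cols)) {
    stop("missing declared column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!tl_name %in% traits || trait_kinds[[tl_name]] != "morphometric") {
    stop("total-length trait '", tl_name,
         "' must be a declared morphometric trait", call. = FALSE)
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate specimen_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  vals <- data[traits]
  for (tr in traits) {
    v <- vals[[tr]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in trait '", tr, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop("missing value in trait '", tr, "' at row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    kind <- trait_kinds[[tr]]
    if (kind == "morphometric" && any(v <= 0)) {
      stop("morphometric trait '", tr, "' must be strictly positive (row ",
           which(v <= 0)[1L], ")", call. = FALSE)
    }
    if (kind == "meristic" && (any(v < 0) || any(v != round(v)))) {
      stop("meristic trait '", tr, "' must hold non-negative integers (row ",
           which(v < 0 | v != round(v))[1L], ")", call. = FALSE)
    }
    vals[[tr]] <- v
  }

  structure(
    list(
      data = vals,
      specimen_id = ids,
      species = if (!is.null(species_col)) as.character(data[[species_col]]) else NULL,
      trait_kinds = trait_kinds[traits],
      tl_name = tl_name
    ),
    class = "trait_table"
  )
}

#' Read a trait table from CSV
#'
#' Reads a UTF-8 CSV with a header row and validates it against a trait-kind
#' declaration (see [trait_table()]). The declaration can be given inline or
#' as a config list such as one parsed from YAML/JSON with fields
#' `tl_name`, `id_col`, `species_col`, `morphometric`, `meristic`.
#'
#' @param path path to the CSV file.
#' @param config list with `morphometric` and `meristic` character vectors of
#'   trait names plus `tl_name`, and optionally `id_col`, `species_col`.
#' @return A validated [trait_table()]. Row order is preserved.
#' @export
read_trait_table <- function(path, config) {
  stopifnot(is.list(config))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  kinds <- c(
    stats::setNames(rep("morphometric", length(config$morphometric)), config$morphometric),
    stats::setNames(rep("meristic", length(config$meristic)), config$meristic)
  )
  trait_table(
    df, kinds,
    tl_name = config$tl_name,
    id_col = if (is.null(config$id_col)) "specimen_id" else config$id_col,
    species_col = config$species_col
  )
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", length(x$specimen_id), "specimens x",
      length(x$trait_kinds), "traits (",
      sum(x$trait_kinds == "morphometric"), "morphometric,",
      sum(x$trait_kinds == "meristic"), "meristic ), TL =", x$tl_name, "\n")
  invisible(x)
}
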