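#' Default trait classification
#'
#' The trait set carried through the correlation and network stages:
#' physiological thresholds estimated by this package plus seed mass,
#' site climate summaries, and collection-site geography. The class drives
#' the network exclusion rule (no geographical-geographical and no
#' geographical-climate edges).
#'
#' @return Named character vector mapping trait name to
#'   `"physiological"`, `"climate"` or `"geographical"`.
#' @export
default_trait_classes <- function() {
  c(Tb_G = "physiological", Tb_S = "physiological",
    thetaT_G = "physiological", thetaT_S = "physiological",
    To_G = "physiological", To_S = "physiological",
    psib_G = "physiological", psib_S = "physiological",
    thetaH_G = "physiological", thetaH_S = "physiological",
    Sm = "physiological",
    AT = "climate", T_min = "climate", T_max = "climate",
    AP = "climate", WP = "climate", SP = "climate", AP_sum = "climate",
    Alt = "geographical", Lat = "geographical", Long = "geographical")
}

#' Construct an accession x trait table
#'
#' @param values data frame of numeric trait values with an `accession`
#'   column (or accession row names).
#' @param classes named character vector assigning each trait column to
#'   `"physiological"`, `"climate"` or `"geographical"`; defaults to
#'   [default_trait_classes()] for recognised names.
#' @return A data frame of class `trait_table` with attribute `trait_class`.
#' @export
trait_table <- function(values, classes = default_trait_classes()) {
  stopifnot(is.data.frame(values))
  if ("accession" %in% names(values)) {
    if (anyDuplicated(values$accession))
      st_stop("st_validation_error", "duplicate accession in trait table")
    rownames(values) <- values$accession
    values$accession <- NULL
  }
  traits <- names(values)
  if (!all(vapply(values, is.numeric, logical(1))))
    st_stop("st_validation_error", "trait values must be numeric")
  unknown <- setdiff(traits, names(classes))
  if (length(unknown))
    st_stop("st_validation_error",
            sprintf("no trait class assigned for: %s",
                    paste(unknown, collapse = ", ")))
  cls <- classes[traits]
  if (!all(cls %in% c("physiological", "climate", "geographical")))
    st_stop("st_validation_error", "unknown trait class")
  structure(values, trait_class = cls,
            class = c("trait_table", "data.frame"))
}

#' Read an accession trait table from CSV
#'
#' @param path CSV with an `accession` column and one numeric column per
#'   trait.
#' @param classes trait class map, see [trait_table()].
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path, classes = default_trait_classes()) {
  if (!file.exists(path))
    st_stop("st_io_error", sprintf("trait table not found: %s", path))
  trait_table(read.csv(path, stringsAsFactors = FALSE), classes)
}

#' @export
print.trait_table <- function(x, ...) {
  cls <- attr(x, "trait_class")
  cat(sprintf("<trait_table> %d accessions x %d traits (%d physiological, %d climate, %d geographical)\n",
              nrow(x), ncol(x), sum(cls == "physiological"),
              sum(cls == "climate"), sum(cls == "geographical")))
  print.data.frame(x, ...)
  invisible(x)
}
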