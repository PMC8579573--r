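# Physicochemical property scales used by the PseAAC encoder.
#
# A scale is 20 numbers, one per amino acid. Before entering any
# correlation product the raw values are standardized to mean 0 and
# population standard deviation 1 (divisor 20) over the 20 amino acids.

#' Standardize a property scale over the 20 amino acids
#'
#' Centers and scales the 20 raw values to mean 0 and population standard
#' deviation 1 (sum of squared deviations divided by 20, not 19).
#'
#' @param raw Named numeric vector with one finite value per amino acid in
#'   [AMINO_ACIDS].
#' @param name Scale name carried along for feature labels.
#' @return Object of class `property_scale`: list with `name`, `raw`,
#'   `standardized` (both named numeric, ordered as [AMINO_ACIDS]).
#' @export
standardize_scale <- function(raw, name = "scale") {
  missing <- setdiff(AMINO_ACIDS, names(raw))
  if (length(missing) > 0L) {
    stop("scale '", name, "' is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- as.numeric(raw[AMINO_ACIDS])
  names(raw) <- AMINO_ACIDS
  if (any(!is.finite(raw))) stop("scale '", name, "' has non-finite values")
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))
  if (sigma == 0) stop("scale '", name, "' has zero variance")
  std <- (raw - mu) / sigma
  structure(list(name = name, raw = raw, standardized = std),
            class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat("<property_scale>", x$name, "\n")
  print(round(x$standardized, 3))
  invisible(x)
}

#' Load property scales from a TSV table
#'
#' The table must have an `aa` column (20 one-letter codes) and one numeric
#' column per scale; every column is standardized with
#' [standardize_scale()].
#'
#' @param path Path to the TSV file.
#' @return Named list of `property_scale` objects, in column order.
#' @export
load_property_scales <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!("aa" %in% names(df))) stop("scale table needs an 'aa' column")
  cols <- setdiff(names(df), "aa")
  if (length(cols) == 0L) stop("scale table has no scale columns")
  out <- lapply(cols, function(cn) {
    v <- df[[cn]]
    names(v) <- toupper(df$aa)
    standardize_scale(v, name = cn)
  })
  names(out) <- cols
  out
}

#' The nine default physicochemical property scales
#'
#' Hydrophobicity (Kyte--Doolittle hydropathy), hydrophilicity
#' (Hopp--Woods), average residue mass, pK1 (alpha-COOH), pK2 (alpha-NH3+)
#' and isoelectric point pI are the classic biochemistry reference values.
#' The remaining three columns are documented proxies, not canonical
#' published "rigidity"/"irreplaceability" indices: flexibility is the
#' average flexibility index of Bhaskaran and Ponnuswamy; rigidity is
#' proxied by the Chou--Fasman helix conformational parameter (helix
#' formers are conformationally stiff); irreplaceability is proxied by the
#' negated Dayhoff relative mutability (rarely substituted residues are
#' hard to replace). Because standardization removes location and scale,
#' only the ordering/shape of each column matters to the encoder, and any
#' column can be overridden by supplying your own table to
#' [load_property_scales()]. Numeric acceptance checks of the encoder use
#' toy scales, never this table.
#'
#' @return Named list of 9 `property_scale` objects.
#' @export
default_property_scales <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "property_scales_default.tsv",
                          package = "amyloscan", mustWork = TRUE)
      cache <<- load_property_scales(path)
    }
    cache
  }
})
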