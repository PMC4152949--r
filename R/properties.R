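#' Dinucleotide structural-property tables
#'
#' A `property_table` stores mu structural properties (rows) for the 16
#' dinucleotides (columns, fixed lexicographic order AA, AC, ..., TT).
#' The PseDNC correlation factors are computed from the standardized form,
#' in which each property row is z-scored across the 16 dinucleotides with
#' the population (divide-by-16) standard deviation so that every property
#' contributes on a common scale.
#'
#' @param values numeric matrix, properties x 16 dinucleotides; column
#'   names must be the 16 dinucleotides (any order; they are rearranged to
#'   lexicographic), row names the property names.
#' @param standardized whether `values` are already z-scored.
#' @return an object of class `property_table`.
#' @export
property_table <- function(values, standardized = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      !setequal(colnames(values), DINUCLEOTIDES) || ncol(values) != 16L)
    stop("`values` must have exactly the 16 dinucleotides ",
         "AA...TT as column names")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("property", seq_len(nrow(values)))
  values <- values[, DINUCLEOTIDES, drop = FALSE]
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("property table contains missing values")
  structure(list(values = values, standardized = isTRUE(standardized)),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table> ", nrow(x$values), " properties (",
      paste(rownames(x$values), collapse = ", "), "), ",
      if (x$standardized) "standardized" else "raw", " values\n", sep = "")
  invisible(x)
}

#' Z-score a property table across the 16 dinucleotides
#'
#' Each property row is centered and scaled by its population standard
#' deviation over the 16 dinucleotide values. Standardizing an already
#' standardized table is a no-op up to floating-point error.
#'
#' @param table a [property_table()].
#' @return a standardized [property_table()].
#' @export
standardize_properties <- function(table) {
  stopifnot(inherits(table, "property_table"))
  v <- table$values
  m <- rowMeans(v)
  s <- sqrt(rowMeans((v - m)^2))
  degenerate <- s < 1e-12
  if (any(degenerate))
    stop("degenerate property (zero variance across dinucleotides): ",
         paste(rownames(v)[degenerate], collapse = ", "))
  property_table((v - m) / s, standardized = TRUE)
}

#' Read a property table from TSV
#'
#' Expected dialect: optional comment lines starting with `#`, a header
#' `dinucleotide<TAB><property names...>`, then 16 data rows. A pragma
#' line `#standardized=true` marks the values as already z-scored.
#'
#' @param path TSV file path.
#' @return a [property_table()] (raw unless the pragma is present).
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 50L)
  standardized <- any(grepl("^#\\s*standardized\\s*=\\s*true\\s*$",
                            head_lines, ignore.case = TRUE))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (tolower(names(df)[1]) != "dinucleotide")
    stop("first column must be 'dinucleotide'")
  v <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(v) <- toupper(df[[1]])
  property_table(v, standardized = standardized)
}

#' The bundled default property table
#'
#' Loads and standardizes the six-property table shipped with the package
#' (twist, tilt, roll, shift, slide, rise). The shipped values are a
#' synthetic stand-in constructed to lie in realistic crystallographic
#' ranges with reverse-complement symmetry; they are not the measured
#' table of any published study. Supply a published table through
#' [read_property_table()] when reproducing published results.
#'
#' @return a standardized [property_table()] with six properties.
#' @export
default_property_table <- function() {
  path <- system.file("extdata", "dinucleotide_properties_synthetic.tsv",
                      package = "psedhs", mustWork = TRUE)
  standardize_properties(read_property_table(path))
}

#' Structural correlation distance between two dinucleotides
#'
#' `theta_pair(x, y)` is the mean squared difference of the standardized
#' property values of `x` and `y` over the mu properties: the type-I
#' pseudo-composition correlation function. It is symmetric, non-negative
#' and zero for identical dinucleotides.
#'
#' @param x,y dinucleotide strings, e.g. `"AC"`.
#' @param table a standardized [property_table()].
#' @return a single non-negative number.
#' @export
theta_pair <- function(x, y, table = default_property_table()) {
  table <- ensure_standardized(table)
  x <- toupper(x); y <- toupper(y)
  if (!x %in% DINUCLEOTIDES) stop("unknown dinucleotide: ", x)
  if (!y %in% DINUCLEOTIDES) stop("unknown dinucleotide: ", y)
  mean((table$values[, x] - table$values[, y])^2)
}

# 16 x 16 matrix of theta_pair values for fast lookup.
theta_matrix <- function(table) {
  v <- table$values
  sq <- colSums(v^2)
  th <- (outer(sq, sq, "+") - 2 * crossprod(v)) / nrow(v)
  th[th < 0] <- 0  # clip tiny negative rounding residue
  th
}

ensure_standardized <- function(table) {
  stopifnot(inherits(table, "property_table"))
  if (table$standardized) table else standardize_properties(table)
}

#' Checksum of a property table
#'
#' MD5 digest of the full-precision standardized values, used to refuse
#' predicting with a model whose training-time property table differs.
#'
#' @param table a [property_table()].
#' @return a character MD5 string.
#' @export
property_checksum <- function(table) {
  table <- ensure_standardized(table)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(rownames(table$values),
               format(table$values, digits = 17)), tmp)
  unname(tools::md5sum(tmp))
}
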