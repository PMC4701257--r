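#' Elements commonly quantified in propolis reference chemistry
#'
#' Default element set: the six mineral elements and five potentially toxic
#' trace elements routinely reported for propolis, in conventional order.
#' @export
nir_elements <- c("Al", "Ca", "Fe", "K", "Mg", "P",
                  "Cr", "Cu", "Ni", "Pb", "Zn")

#' Construct a spectra set
#'
#' A `spectra_set` holds absorbance spectra, recorded as log(1/R), on a
#' common strictly increasing and uniformly spaced wavelength grid.  Rows of
#' the absorbance matrix are individual scans; when the same physical sample
#' was scanned repeatedly, `replicate_of` maps each row to its sample id and
#' [average_replicates()] collapses the rows.
#'
#' @param wavelengths numeric vector of channel wavelengths in nm, strictly
#'   increasing with a uniform step.  The conventional fiber-optic probe grid
#'   is 1100--2000 nm in 2 nm steps (451 channels).
#' @param absorbance numeric matrix, one row per scan, one column per channel.
#' @param sample_ids character vector of row identifiers.  Must be unique
#'   unless `replicate_of` is supplied.
#' @param replicate_of optional character vector mapping each row to the
#'   sample it replicates; rows sharing a value are replicates of one sample.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids,
                        replicate_of = NULL) {
  absorbance <- as.matrix(absorbance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(absorbance) != length(wavelengths))
    stop("absorbance has ", ncol(absorbance), " columns but ",
         length(wavelengths), " wavelengths were given")
  if (nrow(absorbance) != length(sample_ids))
    stop("absorbance has ", nrow(absorbance), " rows but ",
         length(sample_ids), " sample ids were given")
  check_grid(wavelengths)
  if (!all(is.finite(absorbance)))
    stop("absorbance values must all be finite")
  sample_ids <- as.character(sample_ids)
  if (is.null(replicate_of)) {
    if (anyDuplicated(sample_ids))
      stop("duplicate sample ids without replicate structure: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  } else {
    replicate_of <- as.character(replicate_of)
    if (length(replicate_of) != length(sample_ids))
      stop("replicate_of must have one entry per row")
    if (anyDuplicated(sample_ids))
      stop("duplicate (id, replicate) rows: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(absorbance) <- list(sample_ids, format_wl(wavelengths))
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 sample_ids = sample_ids, replicate_of = replicate_of),
            class = "spectra_set")
}

check_grid <- function(wl) {
  if (length(wl) < 2) stop("wavelength grid needs at least 2 channels")
  d <- diff(wl)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("wavelength grid is not uniform (steps range ",
         signif(min(d), 6), " to ", signif(max(d), 6), " nm)")
  invisible(wl)
}

format_wl <- function(wl) formatC(wl, format = "fg", digits = 10)

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set: ", nrow(x$absorbance), " spectra x ",
      length(x$wavelengths), " channels (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm, step ",
      diff(x$wavelengths)[1], " nm)\n", sep = "")
  if (!is.null(x$replicate_of))
    cat("  replicates of ", length(unique(x$replicate_of)),
        " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by row
#'
#' @param x a `spectra_set`.
#' @param i row index (integer, logical or sample id character vector).
#' @param ... unused.
#' @return A `spectra_set` with the selected rows.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra_set(x$wavelengths, x$absorbance[i, , drop = FALSE],
              x$sample_ids[i],
              if (!is.null(x$replicate_of)) x$replicate_of[i])
}

#' Read a wide-format spectra CSV
#'
#' The expected dialect is one row per scan: a `sample_id` column, an
#' optional `replicate` column, then one column per wavelength whose header
#' is the wavelength in nm.  Decimal separator is ".", encoding UTF-8.
#'
#' @param path path to the CSV file.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("spectra file must have id plus >= 2 channels")
  if (names(df)[1] != "sample_id")
    stop("first column must be 'sample_id', got '", names(df)[1], "'")
  has_rep <- identical(names(df)[2], "replicate")
  first_wl <- if (has_rep) 3L else 2L
  wl <- suppressWarnings(as.numeric(names(df)[first_wl:ncol(df)]))
  if (anyNA(wl))
    stop("wavelength headers must be numeric (nm); offending: ",
         paste(utils::head(names(df)[first_wl:ncol(df)][is.na(wl)], 3),
               collapse = ", "))
  ab <- as.matrix(df[, first_wl:ncol(df), drop = FALSE])
  storage.mode(ab) <- "double"
  if (anyNA(ab)) stop("missing absorbance values in ", path)
  if (has_rep) {
    ids <- paste(df$sample_id, df$replicate, sep = "/")
    spectra_set(wl, ab, ids, replicate_of = as.character(df$sample_id))
  } else {
    spectra_set(wl, ab, as.character(df$sample_id))
  }
}

#' Write a spectra set to wide CSV
#'
#' Inverse of [read_spectra()]: absorbance is written at full precision so a
#' read/write round trip is lossless.
#'
#' @param s a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  ab <- s$absorbance
  if (!is.null(s$replicate_of)) {
    rep_tag <- sub("^.*/", "", s$sample_ids)
    df <- data.frame(sample_id = s$replicate_of, replicate = rep_tag,
                     check.names = FALSE)
  } else {
    df <- data.frame(sample_id = s$sample_ids, check.names = FALSE)
  }
  ab_chr <- apply(ab, 2, function(col) formatC(col, format = "g", digits = 17))
  if (is.null(dim(ab_chr))) ab_chr <- matrix(ab_chr, nrow = nrow(ab))
  colnames(ab_chr) <- format_wl(s$wavelengths)
  utils::write.csv(cbind(df, as.data.frame(ab_chr, check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate scans of each sample
#'
#' Replaces the replicate rows of each sample by their channel-wise
#' arithmetic mean, preserving the order of first occurrence.  Idempotent on
#' a set without replicate structure.
#'
#' @param s a `spectra_set`.
#' @return A `spectra_set` with one row per sample and no replicate map.
#' @export
average_replicates <- function(s) {
  if (is.null(s$replicate_of)) return(s)
  ids <- unique(s$replicate_of)
  ab <- t(vapply(ids, function(id) {
    rows <- s$replicate_of == id
    if (!any(rows)) stop("sample ", id, " has no replicate rows")
    colMeans(s$absorbance[rows, , drop = FALSE])
  }, numeric(length(s$wavelengths))))
  spectra_set(s$wavelengths, ab, ids)
}

#' Construct a reference-chemistry table
#'
#' Holds per-sample element concentrations in mg/kg from the reference
#' method (typically ICP-OES / ICP-MS), with a below-limit-of-quantification
#' (LOQ) flag per cell.  Flagged cells carry `NA` concentration.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param concentrations numeric matrix or data frame, samples x elements,
#'   in mg/kg; `NA` allowed only where `below_loq` is `TRUE`.
#' @param below_loq logical matrix of the same shape (default all `FALSE`).
#' @param loq the quantification limit in mg/kg (default 0.01).
#' @return An object of class `reference_table`.
#' @export
reference_table <- function(sample_ids, concentrations, below_loq = NULL,
                            loq = 0.01) {
  conc <- as.matrix(concentrations)
  storage.mode(conc) <- "double"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(conc) != length(sample_ids))
    stop("concentration rows do not match sample ids")
  if (is.null(colnames(conc))) stop("element columns must be named")
  if (is.null(below_loq))
    below_loq <- matrix(FALSE, nrow(conc), ncol(conc))
  below_loq <- as.matrix(below_loq)
  if (!identical(dim(below_loq), dim(conc)))
    stop("below_loq must match the concentration matrix shape")
  if (any(conc[!below_loq & !is.na(conc)] < 0))
    stop("negative concentrations are not allowed")
  if (any(is.na(conc) & !below_loq))
    stop("missing concentrations must be flagged below-LOQ")
  conc[below_loq] <- NA_real_
  dimnames(conc) <- list(sample_ids, colnames(conc))
  dimnames(below_loq) <- dimnames(conc)
  structure(list(sample_ids = sample_ids, concentrations = conc,
                 below_loq = below_loq, loq = loq),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table: ", length(x$sample_ids), " samples x ",
      ncol(x$concentrations), " elements (",
      paste(colnames(x$concentrations), collapse = ", "),
      "); LOQ ", x$loq, " mg/kg\n", sep = "")
  invisible(x)
}

#' Read a reference-chemistry CSV
#'
#' Expected dialect: `sample_id` column then one numeric column per element;
#' the literal token `Nd` marks a value below the quantification limit.
#'
#' @param path path to the CSV file.
#' @param loq quantification limit in mg/kg (default 0.01).
#' @return A [reference_table()].
#' @export
read_reference <- function(path, loq = 0.01) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "sample_id")
    stop("first column must be 'sample_id', got '", names(df)[1], "'")
  ids <- df$sample_id
  cells <- as.matrix(df[, -1, drop = FALSE])
  nd <- toupper(trimws(cells)) == "ND"
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells),
                                  dimnames = dimnames(cells)))
  if (any(is.na(vals) & !nd))
    stop("non-numeric cell (other than 'Nd') in ", path)
  if (any(vals[!nd] < 0, na.rm = TRUE))
    stop("negative concentration in ", path)
  reference_table(ids, vals, below_loq = nd, loq = loq)
}

#' Write a reference-chemistry table to CSV
#'
#' @param r a `reference_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(r, path) {
  cells <- matrix(formatC(r$concentrations, format = "g", digits = 17),
                  nrow(r$concentrations), dimnames = dimnames(r$concentrations))
  cells[r$below_loq] <- "Nd"
  df <- cbind(data.frame(sample_id = r$sample_ids),
              as.data.frame(cells, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a spectra block with one element of the reference chemistry
#'
#' Matches spectra rows (after replicate averaging) to reference rows by
#' sample id for a single element, producing the X matrix and y vector of a
#' calibration.  Samples present in only one block, or below the LOQ for the
#' element, are dropped (counts reported in the result); alternatively
#' below-LOQ cells can be substituted.
#'
#' @param s a `spectra_set` (replicates are averaged if present).
#' @param r a `reference_table`.
#' @param element element name, e.g. `"K"`.
#' @param below_loq how to treat below-LOQ reference values: `"exclude"`
#'   (default; drop the sample for this element), `"zero"`, or `"half_loq"`.
#' @return A list with `X` (samples x channels), `y` (mg/kg), `ids`,
#'   `wavelengths`, and `dropped` (named counts: `unmatched_spectra`,
#'   `unmatched_reference`, `below_loq`).
#' @export
align_element <- function(s, r, element,
                          below_loq = c("exclude", "zero", "half_loq")) {
  below_loq <- match.arg(below_loq)
  s <- average_replicates(s)
  if (!element %in% colnames(r$concentrations))
    stop("element '", element, "' not in reference table")
  common <- intersect(s$sample_ids, r$sample_ids)
  if (length(common) == 0) stop("no sample ids shared by the two blocks")
  dropped <- c(unmatched_spectra = length(s$sample_ids) - length(common),
               unmatched_reference = length(r$sample_ids) - length(common),
               below_loq = 0L)
  y <- r$concentrations[common, element]
  flag <- r$below_loq[common, element]
  if (below_loq == "exclude") {
    dropped["below_loq"] <- sum(flag)
    keep <- !flag
    common <- common[keep]; y <- y[keep]
  } else {
    y[flag] <- if (below_loq == "zero") 0 else r$loq / 2
  }
  if (length(common) == 0)
    stop("no quantified values of ", element, " remain after alignment")
  list(X = s$absorbance[common, , drop = FALSE], y = unname(y), ids = common,
       wavelengths = s$wavelengths, dropped = dropped)
}
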