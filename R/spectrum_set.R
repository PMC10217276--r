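#' Construct a grading scheme for soluble solid content
#'
#' Defines the three quality grades used throughout the package as half-open
#' \eqn{^\circ}Brix intervals: Grade 1 (top) \eqn{[14, 18)}, Grade 2 (medium)
#' \eqn{[10, 14)}, Grade 3 (poor) \eqn{[8, 10)}. Half-open intervals leave no
#' gap between grades (a value such as 13.995 is unambiguously Grade 2).
#'
#' @param boundaries Increasing numeric vector of cut points, length 4:
#'   \code{c(lo3, lo2, lo1, hi1)}. Defaults to \code{c(8, 10, 14, 18)}.
#' @return An object of class \code{grade_scheme}.
#' @export
#' @examples
#' sch <- grade_scheme()
#' assign_grade(c(14.2, 9.733, 13.995), sch)
grade_scheme <- function(boundaries = c(8, 10, 14, 18)) {
  stopifnot(is.numeric(boundaries), length(boundaries) == 4L,
            all(is.finite(boundaries)), all(diff(boundaries) > 0))
  structure(list(boundaries = as.numeric(boundaries)), class = "grade_scheme")
}

#' Assign quality grades from soluble solid content
#'
#' Maps SSC values (\eqn{^\circ}Brix) to grades 1, 2, 3 under the half-open
#' intervals of a \code{\link{grade_scheme}}. Grade quality is a non-decreasing
#' step function of SSC. Values outside the scheme raise an error rather than
#' being clamped; callers may widen the scheme explicitly.
#'
#' @param ssc Numeric vector of SSC values in \eqn{^\circ}Brix.
#' @param scheme A \code{\link{grade_scheme}}.
#' @return Integer vector of grades in \code{1:3} (1 = highest SSC).
#' @export
assign_grade <- function(ssc, scheme = grade_scheme()) {
  stopifnot(inherits(scheme, "grade_scheme"), is.numeric(ssc), all(is.finite(ssc)))
  b <- scheme$boundaries
  out <- which(ssc < b[1] | ssc >= b[4])
  if (length(out)) {
    stop(sprintf("SSC value(s) outside the grading scheme [%g, %g): %s",
                 b[1], b[4], paste(format(ssc[out[seq_len(min(5, length(out)))]]),
                                   collapse = ", ")))
  }
  ifelse(ssc >= b[3], 1L, ifelse(ssc >= b[2], 2L, 3L))
}

#' Visible-spectrum sample set
#'
#' The container every pipeline stage transforms: an absorbance matrix
#' (samples x wavelengths), the wavelength grid in nm, sample identifiers,
#' and optional SSC labels (\eqn{^\circ}Brix) with derived grades.
#'
#' @param absorbance Numeric matrix, one row per sample, finite values.
#' @param wavelengths Strictly increasing numeric vector (nm); default the
#'   400--800 nm grid at 5 nm steps (81 points).
#' @param sample_ids Character vector of unique ids; defaults to S1, S2, ...
#' @param ssc Optional numeric SSC per sample (NA allowed for unlabelled rows).
#' @param grade Optional integer grades; if omitted and \code{ssc} is present,
#'   grades are assigned from \code{scheme} for in-scheme values.
#' @param scheme \code{\link{grade_scheme}} used for assignment/validation.
#' @return An object of class \code{spectrum_set}.
#' @export
spectrum_set <- function(absorbance, wavelengths = default_grid(),
                         sample_ids = NULL, ssc = NULL, grade = NULL,
                         scheme = grade_scheme()) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample id: %s",
                 sample_ids[duplicated(sample_ids)][1]))
  }
  if (length(sample_ids) != n) stop("sample_ids length must match rows of absorbance")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(absorbance)) {
    stop("wavelengths length must match columns of absorbance")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (!all(is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite absorbance at sample '%s', wavelength %g nm",
                 sample_ids[bad[1]], wavelengths[bad[2]]))
  }
  if (!is.null(ssc)) {
    ssc <- as.numeric(ssc)
    if (length(ssc) != n) stop("ssc length must match sample count")
  }
  if (is.null(grade) && !is.null(ssc)) {
    grade <- rep(NA_integer_, n)
    ok <- !is.na(ssc) & ssc >= scheme$boundaries[1] & ssc < scheme$boundaries[4]
    if (any(ok)) grade[ok] <- assign_grade(ssc[ok], scheme)
  } else if (!is.null(grade)) {
    grade <- as.integer(grade)
    if (length(grade) != n) stop("grade length must match sample count")
    if (!is.null(ssc)) {
      ok <- !is.na(ssc) & !is.na(grade) &
        ssc >= scheme$boundaries[1] & ssc < scheme$boundaries[4]
      if (any(ok) && !all(grade[ok] == assign_grade(ssc[ok], scheme))) {
        stop("grade labels inconsistent with ssc under the active grade scheme")
      }
    }
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format(wavelengths, trim = TRUE)
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 sample_ids = sample_ids, ssc = ssc, grade = grade,
                 scheme = scheme),
            class = "spectrum_set")
}

#' Default visible wavelength grid
#'
#' @return 400 to 800 nm in 5 nm steps (81 points).
#' @export
default_grid <- function() seq(400, 800, by = 5)

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d samples x %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$grade)) {
    tab <- table(factor(x$grade, levels = 1:3))
    cat(sprintf("grades: %s\n",
                paste(sprintf("G%s=%d", names(tab), as.integer(tab)), collapse = " ")))
  }
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$absorbance)

#' Subset a spectrum set by sample index
#'
#' @param x A \code{\link{spectrum_set}}.
#' @param i Row (sample) index.
#' @param ... Ignored.
#' @return A \code{spectrum_set} with the selected samples.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$absorbance[i, , drop = FALSE], x$wavelengths,
               x$sample_ids[i],
               ssc = if (!is.null(x$ssc)) x$ssc[i],
               grade = if (!is.null(x$grade)) x$grade[i],
               scheme = x$scheme)
}

#' Replace the absorbance matrix, keeping labels
#'
#' Internal convenience used by the row-wise pretreatment operators.
#' @noRd
set_absorbance <- function(x, mat, wavelengths = x$wavelengths) {
  spectrum_set(mat, wavelengths, x$sample_ids, ssc = x$ssc, grade = x$grade,
               scheme = x$scheme)
}

#' Read spectra and metadata from CSV
#'
#' The spectra file has header \code{sample_id,400,405,...} and one row per
#' sample; the metadata file has columns \code{sample_id,ssc_brix}. Samples
#' present in the spectra but absent from the metadata carry no SSC.
#'
#' @param spectra_path Path to the absorbance CSV.
#' @param metadata_path Optional path to the metadata CSV.
#' @param scheme \code{\link{grade_scheme}} for grade assignment.
#' @return A validated \code{\link{spectrum_set}}.
#' @export
read_spectra <- function(spectra_path, metadata_path = NULL,
                         scheme = grade_scheme()) {
  df <- utils::read.csv(spectra_path, check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "sample_id") stop("spectra CSV must start with a 'sample_id' column")
  ids <- df$sample_id
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id in %s: %s", spectra_path,
                 ids[duplicated(ids)][1]))
  }
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(wl))) {
    stop(sprintf("non-numeric wavelength header column: '%s'",
                 names(df)[-1][which(is.na(wl))[1]]))
  }
  if (any(diff(wl) <= 0)) stop("wavelength header must be strictly increasing")
  mat <- matrix(NA_real_, nrow(df), length(wl))
  for (j in seq_along(wl)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric absorbance at row %d (sample '%s'), column '%s'",
                   which(is.na(v))[1], ids[which(is.na(v))[1]], names(df)[j + 1L]))
    }
    mat[, j] <- v
  }
  ssc <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, check.names = FALSE)
    if (!all(c("sample_id", "ssc_brix") %in% names(md))) {
      stop("metadata CSV must have columns sample_id, ssc_brix")
    }
    ssc <- md$ssc_brix[match(ids, md$sample_id)]
  }
  spectrum_set(mat, wl, ids, ssc = ssc, scheme = scheme)
}

#' Write spectra and metadata to CSV
#'
#' Inverse of \code{\link{read_spectra}}: values are written with full
#' precision so a read/write round trip reproduces the matrix exactly.
#'
#' @param x A \code{\link{spectrum_set}}.
#' @param spectra_path Output path for the absorbance CSV.
#' @param metadata_path Optional output path for the metadata CSV (written
#'   only when \code{x} carries SSC labels).
#' @return \code{x}, invisibly.
#' @export
write_spectra <- function(x, spectra_path, metadata_path = NULL) {
  stopifnot(inherits(x, "spectrum_set"))
  hdr <- paste(c("sample_id", format(x$wavelengths, trim = TRUE)), collapse = ",")
  rows <- vapply(seq_along(x$sample_ids), function(i) {
    paste(c(x$sample_ids[i],
            format(x$absorbance[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), spectra_path)
  if (!is.null(metadata_path) && !is.null(x$ssc)) {
    writeLines(c("sample_id,ssc_brix",
                 paste(x$sample_ids,
                       format(x$ssc, digits = 17, trim = TRUE, scientific = FALSE),
                       sep = ",")),
               metadata_path)
  }
  invisible(x)
}

#' Stratified split of grade indices
#'
#' Internal worker shared by \code{\link{stratified_split}} and the pipeline
#' (which also splits augmented score tables). Per-grade test counts are the
#' nearest integer of \code{fraction * size}; any remainder against the
#' rounded global count is adjusted on the largest grade.
#'
#' @return list(train, test) of integer indices.
#' @noRd
stratified_split_idx <- function(grade, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (any(is.na(grade))) stop("every sample must carry a grade to stratify")
  counts <- table(grade)
  if (any(counts < 2)) {
    stop(sprintf("cannot stratify: grade %s has fewer than 2 samples",
                 names(counts)[counts < 2][1]))
  }
  n_test <- round(test_fraction * as.integer(counts))
  diff <- round(test_fraction * length(grade)) - sum(n_test)
  if (diff != 0) {
    big <- which.max(counts)
    n_test[big] <- min(max(n_test[big] + diff, 0L), as.integer(counts[big]) - 1L)
  }
  n_test <- pmin(n_test, as.integer(counts) - 1L)
  test <- integer(0)
  with_seed(seed, {
    for (g in seq_along(counts)) {
      members <- which(grade == names(counts)[g])
      if (n_test[g] > 0) test <- c(test, sample(members, n_test[g]))
    }
  })
  list(train = sort(setdiff(seq_along(grade), test)), test = sort(test))
}

#' Stratified train/test split of a spectrum set
#'
#' Random split stratified by grade so each grade's test share matches the
#' requested fraction to within rounding; deterministic for a fixed seed.
#'
#' @param x A \code{\link{spectrum_set}} in which every sample has a grade.
#' @param test_fraction Proportion of samples held out, in (0, 1); the 0.2
#'   default mirrors the conventional 8:2 calibration/prediction split.
#' @param seed Integer seed.
#' @return \code{list(train =, test =)} of \code{spectrum_set}s.
#' @export
stratified_split <- function(x, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(x, "spectrum_set"))
  if (is.null(x$grade)) stop("every sample must carry a grade to stratify")
  idx <- stratified_split_idx(x$grade, test_fraction, seed)
  list(train = x[idx$train], test = x[idx$test])
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
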