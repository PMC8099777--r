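#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased residue strings; names are
#'   record ids (first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("[[:space:][:digit:]]", "", as.character(set)))
  names(seqs) <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  for (i in seq_along(seqs)) .residues(seqs[[i]])  # validate residues
  seqs
}

#' Construct a deconvoluted spectrum
#'
#' Peaks are sorted by mass; peaks closer than `merge_tol` Da are merged with
#' intensities summed (intensity-weighted mean mass).
#'
#' @param mass Neutral monoisotopic masses (Da), as emitted by deisotoping.
#' @param intensity Positive intensities (arbitrary units).
#' @param replicate_id Text id of the technical replicate.
#' @param precursor_mass Optional neutral precursor mass (Da).
#' @param merge_tol Merge tolerance in Da (default 1e-4).
#' @return Object of class `decon_spectrum`: data.frame with columns `mass`
#'   and `intensity` plus attributes.
#' @export
decon_spectrum <- function(mass, intensity, replicate_id = "rep1",
                           precursor_mass = NULL, merge_tol = 1e-4) {
  if (length(mass) != length(intensity)) stop("mass/intensity length mismatch")
  bad <- which(!is.finite(mass) | mass <= 0)
  if (length(bad)) stop("non-positive or non-finite mass at row ", bad[1])
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad)) stop("non-positive or non-finite intensity at row ", bad[1])
  o <- order(mass)
  mass <- mass[o]; intensity <- intensity[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(TRUE, diff(mass) > merge_tol))
    if (max(grp) < length(mass)) {
      m <- vapply(split(seq_along(mass), grp), function(i)
        sum(mass[i] * intensity[i]) / sum(intensity[i]), 0)
      s <- vapply(split(intensity, grp), sum, 0)
      mass <- unname(m); intensity <- unname(s)
    }
  }
  structure(
    data.frame(mass = mass, intensity = intensity),
    replicate_id = as.character(replicate_id),
    precursor_mass = precursor_mass,
    class = c("decon_spectrum", "data.frame")
  )
}

#' Read a deconvoluted peak list from delimited text
#'
#' Accepts comma- or tab-delimited text with at least a mass and an intensity
#' column (XTRACT-style export). A non-numeric first row is treated as a
#' header; columns are matched by name (`mass`/`monoisotopic*`,
#' `intensity`/`abundance`/`height`) or, headerless, taken as columns 1-2.
#'
#' @param path Path to the file.
#' @param replicate_id Replicate id attached to the spectrum (default: file
#'   base name).
#' @param mass_offset Constant added to every mass on read, e.g. -1.007276
#'   for an MH+ dialect (default 0: masses already neutral).
#' @return A `decon_spectrum`.
#' @export
read_peaklist <- function(path, replicate_id = NULL, mass_offset = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 2L) stop("peak list needs at least mass and intensity columns")
  nm <- tolower(names(dt))
  mcol <- which(grepl("^mass$|monoisotopic", nm))[1]
  icol <- which(grepl("intensit|abundance|height", nm))[1]
  if (is.na(mcol) || is.na(icol)) { mcol <- 1L; icol <- 2L }
  mass <- suppressWarnings(as.numeric(dt[[mcol]]))
  intensity <- suppressWarnings(as.numeric(dt[[icol]]))
  bad <- which(is.na(mass) | is.na(intensity))
  if (length(bad)) stop("non-numeric mass/intensity at data row ", bad[1])
  if (is.null(replicate_id))
    replicate_id <- sub("\\.[^.]*$", "", basename(path))
  decon_spectrum(mass + mass_offset, intensity, replicate_id = replicate_id)
}

#' Group replicate spectra into a set
#'
#' @param spectra List of `decon_spectrum` objects.
#' @return Object of class `spectrum_set` (a list).
#' @export
spectrum_set <- function(spectra) {
  stopifnot(all(vapply(spectra, inherits, TRUE, "decon_spectrum")))
  names(spectra) <- vapply(spectra, attr, "", "replicate_id")
  structure(spectra, class = "spectrum_set")
}

#' Spectrum summary statistics and the chance-match probability
#'
#' X is the average number of peaks per 100 Da over the observed mass range
#' of the deconvoluted spectrum; the probability that one theoretical
#' fragment matches by chance is approximated as q = X/100, clamped to
#' (1e-6, 0.99). Ranges below 100 Da are floored to 100 Da.
#'
#' @param spectrum A `decon_spectrum` with >= 2 peaks.
#' @return List with `peak_count`, `mass_range`, `X` and `q`.
#' @export
#' @examples
#' sp <- decon_spectrum(seq(1000, 2995, by = 5), rep(1, 400))
#' compute_spectrum_stats(sp)$X  # 400 peaks / 1995 Da
compute_spectrum_stats <- function(spectrum) {
  if (nrow(spectrum) < 2L) stop("need >= 2 peaks")
  rng <- max(spectrum$mass) - min(spectrum$mass)
  rng <- max(rng, 100)
  X <- nrow(spectrum) / (rng / 100)
  q <- min(max(X / 100, 1e-6), 0.99)
  list(peak_count = nrow(spectrum), mass_range = rng, X = X, q = q)
}

#' Write an analysis result table to TSV or JSON
#'
#' @param results A data.frame (assignments, ranked combinations, quant
#'   rows, ...).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "tsv") {
    num <- vapply(results, is.numeric, TRUE)
    out <- results
    out[num] <- lapply(results[num], function(x) formatC(x, digits = 12,
                                                         format = "g"))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    as.data.frame(data.table::fread(path, sep = "\t"))
  else
    as.data.frame(jsonlite::fromJSON(path))
}

#' Export a PTM ladder as a TSV heatmap matrix
#'
#' Rows are cleavage positions (1..L-1, terminus-local), columns modification
#' counts, values summed matched intensity (0 where absent).
#'
#' @param ladder A `ptm_ladder`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ladder_tsv <- function(ladder, path) {
  m <- ladder_matrix(ladder)
  df <- data.frame(cleavage = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
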