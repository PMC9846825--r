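# Peak-list spectra and Mascot Generic Format (MGF) I/O.

#' Construct a peak-list spectrum
#'
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (positive integer).
#' @param mz,intensity Numeric peak vectors of equal length; peaks are
#'   stored sorted by m/z.
#' @return Object of class `spectrum` with a `peaks` data.frame.
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, mz, intensity) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0, length(mz) == length(intensity))
  precursor_charge <- as.integer(precursor_charge)
  if (precursor_charge < 1L) stop("precursor charge must be >= 1", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(mz)
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge,
                 peaks = data.frame(mz = mz[ord], intensity = intensity[ord])),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  precursor %.4f (%d+)  %d peaks\n",
              x$id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS and CHARGE
#' headers. A block without CHARGE defaults to 2+ with a warning; a block
#' without PEPMASS is a format error naming the block.
#'
#' @param path Path to an MGF file.
#' @return List of `spectrum` objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), headers, value = TRUE)
      if (!length(hit)) return(NULL)
      sub(paste0("^", key, "="), "", hit[1])
    }
    title <- get("TITLE")
    if (is.null(title)) title <- sprintf("spectrum_%d", k)
    pepmass <- get("PEPMASS")
    if (is.null(pepmass)) {
      stop("MGF block '", title, "' (block ", k, ") has no PEPMASS",
           call. = FALSE)
    }
    precursor_mz <- as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
    ch <- get("CHARGE")
    if (is.null(ch)) {
      warning("MGF block '", title, "' has no CHARGE; defaulting to 2+",
              call. = FALSE)
      charge <- 2L
    } else {
      charge <- as.integer(gsub("[^0-9]", "", ch))
    }
    peak_lines <- block[!is_header]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[\\s\t]+", perl = TRUE)
      mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
      intensity <- vapply(fields, function(f) {
        if (length(f) >= 2) as.numeric(f[2]) else 1
      }, numeric(1))
    } else {
      mz <- numeric(0); intensity <- numeric(0)
    }
    out[[k]] <- spectrum(title, precursor_mz, charge, mz, intensity)
  }
  out
}

#' Write spectra to an MGF file
#'
#' m/z values are written with 5 decimals and intensities with 4
#' significant digits, so `write_mgf()` then [read_mgf()] is an identity
#' on m/z to 4 decimals. Output is byte-deterministic for identical input.
#'
#' @param spectra List of `spectrum` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$id),
                 sprintf("PEPMASS=%.5f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("%.5f %.6g", s$peaks$mz, s$peaks$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}
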