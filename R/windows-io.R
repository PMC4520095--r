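#' Construct a table of phosphopeptide windows
#'
#' A `phospho_windows` object is a data.frame with one row per
#' serine-centered phosphopeptide window and columns `species`, `dataset`,
#' `protein`, `site` (1-based phosphosite position in the source protein),
#' `window` (amino-acid string, length <= width), `offset` (0-based index of
#' the phospho-residue within the window) and `wid` (unique window id used to
#' map n-grams back to their source windows).
#'
#' Windows are truncated, never padded, at protein termini, so `offset` is 10
#' for a canonical 21-mer and smaller when the N-terminal side was truncated.
#'
#' @param species,dataset,protein character vectors of provenance labels.
#' @param site integer vector, 1-based phosphosite positions.
#' @param window character vector of window sequences (20-letter alphabet
#'   plus `X` for unknown residues).
#' @param offset integer vector, 0-based offset of the phosphosite in the
#'   window.
#' @param wid optional unique window ids; generated when omitted.
#' @param strict if `TRUE` (default) the residue at `offset` must be `S`.
#' @param center central residue(s) admitted in strict mode; default `"S"`.
#'   Set e.g. `c("S","T","Y")` to admit other phosphoacceptors.
#' @return a `phospho_windows` data.frame.
#' @export
phospho_windows <- function(species, dataset, protein, site, window,
                            offset, wid = NULL,
                            strict = TRUE, center = "S") {
  x <- data.frame(species = as.character(species),
                  dataset = as.character(dataset),
                  protein = as.character(protein),
                  site = as.integer(site),
                  window = as.character(window),
                  offset = as.integer(offset),
                  stringsAsFactors = FALSE)
  x$wid <- if (is.null(wid)) sprintf("w%d", seq_len(nrow(x)))
           else as.character(wid)
  validate_windows(x, strict = strict, center = center)
  class(x) <- c("phospho_windows", "data.frame")
  x
}

validate_windows <- function(x, strict = TRUE, center = "S") {
  n <- nrow(x)
  if (n == 0L) return(invisible(x))
  len <- nchar(x$window)
  bad <- which(len < 1L | len > 21L | x$offset < 0L | x$offset >= len)
  if (length(bad))
    stop("invalid window geometry (length/offset) at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!.valid_window_chars(x$window))
  if (length(bad))
    stop("window contains characters outside the amino-acid alphabet (+X) ",
         "at row(s): ", paste(head(bad, 5), collapse = ", "))
  if (strict) {
    ctr <- substr(x$window, x$offset + 1L, x$offset + 1L)
    bad <- which(!ctr %in% center)
    if (length(bad))
      stop("central residue is not '", paste(center, collapse = "/"),
           "' at row(s): ", paste(head(bad, 5), collapse = ", "),
           " (found '", paste(unique(ctr[head(bad, 5)]), collapse = "','"),
           "')")
  }
  invisible(x)
}

#' Read a phosphopeptide window table
#'
#' Reads a tab-separated table with header columns `species`, `dataset`,
#' `protein`, `site`, `window` (and optionally `offset`). Lines starting with
#' `#` are ignored. When the `offset` column is absent it is inferred as
#' `min(site - 1, (expected_width - 1)/2)`, which is exact for windows
#' truncated at protein termini.
#'
#' @param path file path.
#' @param expected_width nominal full window width (odd, default 21).
#' @inheritParams phospho_windows
#' @return a `phospho_windows` data.frame in input row order.
#' @export
read_window_table <- function(path, expected_width = 21L,
                              strict = TRUE, center = "S") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("species", "dataset", "protein", "site", "window")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("window table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  site <- as.integer(d$site)
  if (anyNA(site)) stop("non-integer site value in ", path)
  half <- (as.integer(expected_width) - 1L) %/% 2L
  off <- if ("offset" %in% names(d)) as.integer(d$offset)
         else pmin(site - 1L, half)
  wid <- if ("wid" %in% names(d)) d$wid else NULL
  phospho_windows(d$species, d$dataset, d$protein, site, d$window, off,
                  wid = wid, strict = strict, center = center)
}

#' Write a phosphopeptide window table
#'
#' Emits the TSV dialect read by [read_window_table()], including the
#' `offset` and `wid` columns so round trips are lossless.
#'
#' @param x a `phospho_windows` data.frame.
#' @param path output file path.
#' @export
write_window_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# phosphopeptide windows: site is 1-based in the protein,",
               "# offset is the 0-based index of the phosphosite in window"),
             con)
  write.table(x[, c("species", "dataset", "protein", "site", "window",
                    "offset", "wid")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract serine-centered windows from a protein FASTA and a site table
#'
#' Cuts a window of `width` residues centered on each listed phosphosite,
#' truncating (never padding) at protein termini. The site table is a TSV
#' with columns `species`, `dataset`, `protein`, `site`; in strict mode the
#' residue at each site must be a serine.
#'
#' @param fasta path to a protein FASTA file; record ids are the description
#'   line up to the first whitespace.
#' @param sites path to the site table, or a data.frame with the same columns.
#' @param width odd window width (default 21).
#' @inheritParams phospho_windows
#' @return a `phospho_windows` data.frame.
#' @export
extract_windows_from_fasta <- function(fasta, sites, width = 21L,
                                       strict = TRUE, center = "S") {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and positive")
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("extract_windows_from_fasta requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(fasta)
  names(aa) <- sub("\\s.*$", "", names(aa))
  seqs <- setNames(as.character(aa), names(aa))
  s <- if (is.character(sites)) read.delim(sites, comment.char = "#",
                                           stringsAsFactors = FALSE)
       else as.data.frame(sites)
  need <- c("species", "dataset", "protein", "site")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(unique(s$protein), names(seqs))
  if (length(absent))
    stop("protein id(s) absent from FASTA: ",
         paste(head(absent, 5), collapse = ", "))
  prot <- seqs[s$protein]
  plen <- nchar(prot)
  site <- as.integer(s$site)
  if (any(site < 1L | site > plen))
    stop("site position outside protein length for row(s): ",
         paste(head(which(site < 1L | site > plen), 5), collapse = ", "))
  half <- (width - 1L) %/% 2L
  from <- pmax(1L, site - half)
  to <- pmin(plen, site + half)
  win <- substr(prot, from, to)
  phospho_windows(s$species, s$dataset, s$protein, site, win,
                  offset = site - from, strict = strict, center = center)
}
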