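#' Construct and validate a genetic map
#'
#' A genetic map is a data frame with columns `marker`, `chromosome` and
#' `position` (centimorgans from the top of the chromosome). Positions must be
#' strictly increasing within a chromosome and marker names unique
#' genome-wide.
#'
#' @param marker Character vector of marker names.
#' @param chromosome Chromosome identifier per marker (character or integer).
#' @param position Numeric position in cM.
#' @return A validated `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(marker, chromosome, position) {
  map <- data.frame(
    marker = as.character(marker),
    chromosome = as.character(chromosome),
    position = as.numeric(position),
    stringsAsFactors = FALSE
  )
  validate_map(map)
}

#' @rdname genetic_map
#' @param map A data frame with columns `marker`, `chromosome`, `position`.
#' @export
validate_map <- function(map) {
  need <- c("marker", "chromosome", "position")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(map) == 0L) stop("map has no markers", call. = FALSE)
  if (anyDuplicated(map$marker)) {
    stop("marker names must be unique genome-wide", call. = FALSE)
  }
  if (any(!is.finite(map$position)) || any(map$position < 0)) {
    stop("marker positions must be finite and non-negative", call. = FALSE)
  }
  for (chr in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == chr]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop(sprintf("positions on chromosome %s are not strictly increasing",
                   chr), call. = FALSE)
    }
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulate a marker map for an inbred-cross genome
#'
#' Places `n_markers` markers across chromosomes in proportion to their
#' genetic length, evenly spaced with a small uniform jitter. Defaults
#' emulate a five-chromosome Arabidopsis genome (~485 cM) genotyped at 234
#' markers, the scale of classic Cvi x Ler RIL marker sets.
#'
#' @param chr_lengths Named numeric vector of chromosome lengths in cM.
#' @param n_markers Total marker count, allocated proportionally to length.
#' @param jitter_frac Jitter as a fraction of the local inter-marker spacing.
#' @param seed Integer seed.
#' @return A `genetic_map`.
#' @export
sim_genetic_map <- function(chr_lengths = c("1" = 135, "2" = 75, "3" = 90,
                                            "4" = 80, "5" = 105),
                            n_markers = 234, jitter_frac = 0.25, seed = 1) {
  stopifnot(length(chr_lengths) >= 1, all(chr_lengths > 0), n_markers >= length(chr_lengths))
  if (is.null(names(chr_lengths))) names(chr_lengths) <- seq_along(chr_lengths)
  alloc <- round(n_markers * chr_lengths / sum(chr_lengths))
  alloc <- pmax(alloc, 2L)   # keeps chromosome names
  # adjust rounding drift on the longest chromosome
  alloc[which.max(chr_lengths)] <- alloc[which.max(chr_lengths)] +
    (n_markers - sum(alloc))
  with_seed(substream_seed(seed, "map"), {
    pieces <- lapply(names(chr_lengths), function(chr) {
      m <- alloc[[chr]]
      len <- chr_lengths[[chr]]
      pos <- seq(0, len, length.out = m)
      if (m > 2L) {
        gap <- len / (m - 1)
        mid <- pos[2:(m - 1)] +
          stats::runif(m - 2L, -jitter_frac * gap, jitter_frac * gap)
        pos <- c(0, sort(mid), len)
      }
      data.frame(
        marker = sprintf("c%s_m%03d", chr, seq_len(m)),
        chromosome = chr,
        position = round(pos, 3),
        stringsAsFactors = FALSE
      )
    })
    validate_map(do.call(rbind, pieces))
  })
}

# split a map (or pseudomarker grid) into per-chromosome pieces, in map order
split_by_chr <- function(map) {
  split(map, factor(map$chromosome, levels = unique(map$chromosome)))
}

#' Haldane map function and RIL-by-selfing recombination
#'
#' `haldane_r()` converts a genetic distance in cM to a recombination fraction
#' assuming no interference; `ril_selfing_R()` converts that meiotic fraction
#' to the fraction observed between fully inbred RIL genomes, R = 2r/(1+2r).
#'
#' @param d_cM Genetic distance in centimorgans.
#' @param r Meiotic recombination fraction.
#' @return Recombination fraction in [0, 0.5] (`haldane_r`) or [0, 2/3]
#'   (`ril_selfing_R`).
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' @rdname haldane_r
#' @export
ril_selfing_R <- function(r) 2 * r / (1 + 2 * r)
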