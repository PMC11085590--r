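#' Insert pseudomarkers into a genetic map
#'
#' Builds the evaluation grid for genome scans: all true markers plus
#' synthetic positions so that no inter-marker gap exceeds `step` cM. Each
#' gap is subdivided evenly into ceiling(gap/step) pieces, so pseudomarker
#' positions (and names, `c<chr>_loc<pos>`) are deterministic.
#'
#' @param map A `genetic_map`.
#' @param step Maximum grid spacing in cM (> 0). Default 1.
#' @return data.frame(marker, chromosome, position, is_pseudo) of class
#'   `scan_grid`, ordered by chromosome then position.
#' @export
insert_pseudomarkers <- function(map, step = 1) {
  map <- validate_map(map)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  pieces <- lapply(split_by_chr(map), function(chr) {
    pos <- chr$position
    out_pos <- pos[1]
    out_name <- chr$marker[1]
    out_pseudo <- FALSE
    if (nrow(chr) > 1L) {
      for (j in seq_len(nrow(chr) - 1L)) {
        gap <- pos[j + 1L] - pos[j]
        n_sub <- ceiling(gap / step - 1e-9)
        if (n_sub > 1L) {
          mids <- pos[j] + gap * seq_len(n_sub - 1L) / n_sub
          out_pos <- c(out_pos, mids)
          out_name <- c(out_name,
                        sprintf("c%s_loc%.3f", chr$chromosome[1], mids))
          out_pseudo <- c(out_pseudo, rep(TRUE, n_sub - 1L))
        }
        out_pos <- c(out_pos, pos[j + 1L])
        out_name <- c(out_name, chr$marker[j + 1L])
        out_pseudo <- c(out_pseudo, FALSE)
      }
    }
    data.frame(marker = out_name, chromosome = chr$chromosome[1],
               position = out_pos, is_pseudo = out_pseudo,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  class(grid) <- c("scan_grid", "data.frame")
  grid
}

#' HMM conditional genotype probabilities for a selfed RIL cross
#'
#' Forward-backward over hidden states {AA, BB} at every grid position.
#' Transitions between adjacent positions d cM apart use the RIL-by-selfing
#' recombination fraction R = 2r/(1+2r) with Haldane r; emissions allow a
#' symmetric genotyping error rate (P(observe g | state g) = 1 - error_rate),
#' and missing observations (or pseudomarkers) are uninformative. Chromosomes
#' are independent; the stationary initial distribution is (1/2, 1/2).
#'
#' @param genotypes RIL x marker character matrix ("AA"/"BB"/NA).
#' @param map `genetic_map` covering the genotyped markers.
#' @param grid Scan grid from [insert_pseudomarkers()]; defaults to a 1-cM
#'   grid over `map`.
#' @param error_rate Genotyping error probability in [0, 0.5).
#' @return 3-d array RIL x position x genotype ("AA","BB") of class
#'   `genoprobs`, rows summing to 1, with the grid attached as attribute
#'   `"grid"`.
#' @export
genotype_probabilities <- function(genotypes, map,
                                   grid = insert_pseudomarkers(map, 1),
                                   error_rate = 0.001) {
  map <- validate_map(map)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("`error_rate` must be in [0, 0.5)", call. = FALSE)
  }
  if (!all(map$marker %in% colnames(genotypes))) {
    stop("genotypes are missing columns for some mapped markers", call. = FALSE)
  }
  bad <- !(genotypes %in% c("AA", "BB") | is.na(genotypes))
  if (any(bad)) {
    cells <- which(bad, arr.ind = TRUE)
    stop("invalid genotype code(s) at: ",
         paste(sprintf("%s/%s", rownames(genotypes)[cells[, 1]],
                       colnames(genotypes)[cells[, 2]])[seq_len(min(5, nrow(cells)))],
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(genotypes)
  probs <- array(NA_real_, c(n, nrow(grid), 2L),
                 dimnames = list(rownames(genotypes), grid$marker,
                                 c("AA", "BB")))
  col_of <- match(grid$marker, colnames(genotypes))
  for (chr_grid in split_by_chr(grid)) {
    idx <- match(chr_grid$marker, grid$marker)
    P <- nrow(chr_grid)
    # observation matrix: NA at pseudomarkers / missing calls
    obs <- matrix(NA_character_, n, P)
    real <- !chr_grid$is_pseudo
    obs[, real] <- genotypes[, col_of[idx[real]], drop = FALSE]
    # emission probabilities for state AA and state BB, vectorised over RILs
    e_aa <- matrix(1, n, P); e_bb <- matrix(1, n, P)
    e_aa[!is.na(obs) & obs == "AA"] <- 1 - error_rate
    e_aa[!is.na(obs) & obs == "BB"] <- error_rate
    e_bb[!is.na(obs) & obs == "BB"] <- 1 - error_rate
    e_bb[!is.na(obs) & obs == "AA"] <- error_rate
    R <- if (P > 1L) ril_selfing_R(haldane_r(diff(chr_grid$position))) else numeric(0)
    # forward pass (scaled)
    f_aa <- matrix(NA_real_, n, P); f_bb <- matrix(NA_real_, n, P)
    f_aa[, 1] <- 0.5 * e_aa[, 1]; f_bb[, 1] <- 0.5 * e_bb[, 1]
    s <- f_aa[, 1] + f_bb[, 1]
    f_aa[, 1] <- f_aa[, 1] / s; f_bb[, 1] <- f_bb[, 1] / s
    if (P > 1L) for (j in 2:P) {
      Rj <- R[j - 1L]
      pa <- (f_aa[, j - 1L] * (1 - Rj) + f_bb[, j - 1L] * Rj) * e_aa[, j]
      pb <- (f_aa[, j - 1L] * Rj + f_bb[, j - 1L] * (1 - Rj)) * e_bb[, j]
      s <- pa + pb
      f_aa[, j] <- pa / s; f_bb[, j] <- pb / s
    }
    # backward pass (scaled)
    b_aa <- matrix(1, n, P); b_bb <- matrix(1, n, P)
    if (P > 1L) for (j in (P - 1L):1L) {
      Rj <- R[j]
      ea <- e_aa[, j + 1L] * b_aa[, j + 1L]
      eb <- e_bb[, j + 1L] * b_bb[, j + 1L]
      pa <- (1 - Rj) * ea + Rj * eb
      pb <- Rj * ea + (1 - Rj) * eb
      s <- pa + pb
      b_aa[, j] <- pa / s; b_bb[, j] <- pb / s
    }
    post_aa <- f_aa * b_aa
    post_bb <- f_bb * b_bb
    s <- post_aa + post_bb
    probs[, idx, "AA"] <- post_aa / s
    probs[, idx, "BB"] <- post_bb / s
  }
  structure(probs, grid = grid, class = "genoprobs")
}

# P(BB) matrix (RIL x position) from a genoprobs array
pbb_matrix <- function(genoprobs) {
  m <- genoprobs[, , "BB", drop = FALSE]
  dim(m) <- dim(genoprobs)[1:2]
  dimnames(m) <- dimnames(genoprobs)[1:2]
  m
}

# vectorised Haley-Knott LOD for one phenotype against all positions.
# y: length-n numeric (no NA); pbb: n x P matrix. Returns length-P LOD.
hk_lod_vector <- function(pbb, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy <= 0) return(rep(0, ncol(pbb)))
  pc <- sweep(pbb, 2L, colMeans(pbb))
  sxx <- colSums(pc^2)
  sxy <- as.numeric(crossprod(pc, yc))
  rss1 <- syy - ifelse(sxx > 1e-12, sxy^2 / sxx, 0)
  rss1 <- pmax(rss1, syy * 1e-12)
  pmax((n / 2) * log10(syy / rss1), 0)
}

#' Single-QTL Haley-Knott genome scan
#'
#' At every grid position, regresses the phenotype on the conditional
#' probability P(BB) (for a two-class inbred cross, [P(AA), P(BB)] is
#' collinear with the intercept, so one regressor carries the model).
#' LOD = (N/2) log10(RSS0 / RSS1) against the intercept-only model. RILs with
#' missing phenotype are dropped trait-wise; a zero-variance phenotype gives
#' LOD identically 0.
#'
#' @param genoprobs `genoprobs` array from [genotype_probabilities()].
#' @param phenotype Numeric vector named by RIL, or a RIL x trait matrix /
#'   data.frame (numeric columns).
#' @return data.frame(chromosome, position, marker, then one LOD column per
#'   trait) of class `lod_profile`, with `n_used` per trait as an attribute.
#' @export
hk_scan <- function(genoprobs, phenotype) {
  grid <- attr(genoprobs, "grid")
  pbb <- pbb_matrix(genoprobs)
  ph <- if (is.null(dim(phenotype))) {
    matrix(phenotype, ncol = 1L, dimnames = list(names(phenotype), "lod"))
  } else as.matrix(as.data.frame(phenotype))
  if (is.null(rownames(ph)) || all(rownames(ph) == as.character(seq_len(nrow(ph))))) {
    if (nrow(ph) != nrow(pbb)) {
      stop("phenotype must be named by RIL or match genoprobs rows", call. = FALSE)
    }
    rownames(ph) <- rownames(pbb)
  }
  ph <- ph[rownames(pbb), , drop = FALSE]
  out <- data.frame(chromosome = grid$chromosome, position = grid$position,
                    marker = grid$marker, stringsAsFactors = FALSE)
  n_used <- integer(ncol(ph))
  for (j in seq_len(ncol(ph))) {
    y <- ph[, j]
    keep <- is.finite(y)
    if (sum(keep) < 10L) {
      stop(sprintf("trait '%s' has fewer than 10 non-missing phenotypes",
                   colnames(ph)[j]), call. = FALSE)
    }
    out[[colnames(ph)[j]]] <- hk_lod_vector(pbb[keep, , drop = FALSE], y[keep])
    n_used[j] <- sum(keep)
  }
  attr(out, "n_used") <- stats::setNames(n_used, colnames(ph))
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Genome-wide permutation threshold for a Haley-Knott scan
#'
#' Permutes the phenotype vector against the RIL rows `n_perm` times (whole-
#' vector permutation preserves the genotype LD structure), records each
#' genome-wide maximum LOD, and returns the empirical `quantile`. Seeded and
#' reproducible; permutations are evaluated in a single batched matrix
#' product.
#'
#' @inheritParams hk_scan
#' @param phenotype Numeric vector named by RIL (one trait).
#' @param n_perm Number of permutations (>= 100).
#' @param quantile Probability for the empirical quantile (default 0.95).
#' @param seed Integer seed.
#' @return Threshold LOD (scalar) with the permuted maxima as attribute
#'   `"max_lods"`.
#' @export
permutation_threshold <- function(genoprobs, phenotype, n_perm = 1000,
                                  quantile = 0.95, seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  pbb <- pbb_matrix(genoprobs)
  y <- phenotype
  if (!is.null(names(y))) y <- y[rownames(pbb)]
  keep <- is.finite(y)
  if (sum(keep) < 10L) stop("fewer than 10 non-missing phenotypes", call. = FALSE)
  y <- y[keep]
  pbb <- pbb[keep, , drop = FALSE]
  n <- length(y)
  pc <- sweep(pbb, 2L, colMeans(pbb))
  sxx <- colSums(pc^2)
  ok <- sxx > 1e-12
  maxlod <- with_seed(substream_seed(seed, "perm"), {
    Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
    Yc <- sweep(Y, 2L, colMeans(Y))
    syy <- colSums(Yc^2)
    SXY <- crossprod(pc[, ok, drop = FALSE], Yc)      # P_ok x n_perm
    RSS1 <- sweep(-SXY^2 / sxx[ok], 2L, syy, "+")
    RSS1 <- pmax(RSS1, rep(syy * 1e-12, each = sum(ok)))
    LOD <- (n / 2) * log10(sweep(1 / RSS1, 2L, syy, "*"))
    apply(pmax(LOD, 0), 2L, max)
  })
  structure(as.numeric(stats::quantile(maxlod, quantile)),
            max_lods = maxlod)
}

#' Locate significant QTL peaks with 1.5-LOD support intervals
#'
#' Per chromosome and trait, reports every peak with LOD >= `threshold`
#' (ties broken to the leftmost grid position). The support interval is the
#' contiguous region around the peak where LOD >= peak - `drop`. Multiple
#' peaks on one chromosome are accepted only if the LOD dips by more than
#' `drop` between them. The additive effect is half the difference of the
#' fitted genotype-class means at the peak (Haley-Knott slope / 2, Cvi-like
#' "BB" minus Ler-like "AA" orientation).
#'
#' @param profile `lod_profile` from [hk_scan()] (one or more trait columns).
#' @param genoprobs The `genoprobs` used for the scan (for effect estimates).
#' @param phenotype The phenotype vector/matrix used for the scan.
#' @param threshold Significance threshold (LOD >= threshold is significant).
#' @param drop LOD-unit drop defining the support interval. Default 1.5.
#' @return data.frame: trait, chromosome, position, lod, ci_lo, ci_hi,
#'   effect. Zero rows if nothing is significant.
#' @export
find_peaks <- function(profile, genoprobs, phenotype, threshold, drop = 1.5) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  pbb <- pbb_matrix(genoprobs)
  ph <- if (is.null(dim(phenotype))) {
    matrix(phenotype, ncol = 1L, dimnames = list(names(phenotype), "lod"))
  } else as.matrix(as.data.frame(phenotype))
  if (is.null(rownames(ph)) || all(rownames(ph) == as.character(seq_len(nrow(ph))))) {
    rownames(ph) <- rownames(pbb)
  }
  traits <- setdiff(names(profile), c("chromosome", "position", "marker"))
  hits <- list()
  for (trait in traits) {
    y_all <- ph[rownames(pbb), trait]
    for (chr in unique(profile$chromosome)) {
      sel <- which(profile$chromosome == chr)
      lod <- profile[[trait]][sel]
      accepted <- integer(0)
      cand <- order(lod, decreasing = TRUE)
      for (i in cand) {
        if (lod[i] < threshold) break
        separated <- all(vapply(accepted, function(a) {
          rng <- if (a < i) a:i else i:a
          min(lod[rng]) <= min(lod[i], lod[a]) - drop
        }, logical(1)))
        if (i %in% accepted || !separated) next
        # leftmost tie within this peak's plateau
        accepted <- c(accepted, i)
      }
      for (i in accepted) {
        # contiguous support region around the peak
        lo <- i
        while (lo > 1L && lod[lo - 1L] >= lod[i] - drop) lo <- lo - 1L
        hi <- i
        while (hi < length(sel) && lod[hi + 1L] >= lod[i] - drop) hi <- hi + 1L
        # leftmost grid position among exact ties at the peak value
        plateau <- which(lod[lo:hi] == lod[i]) + lo - 1L
        i_rep <- plateau[1L]
        pos_idx <- sel[i_rep]
        y <- y_all
        keep <- is.finite(y)
        slope <- {
          p <- pbb[keep, pos_idx]
          if (stats::var(p) > 0) stats::cov(p, y[keep]) / stats::var(p) else 0
        }
        hits[[length(hits) + 1L]] <- data.frame(
          trait = trait, chromosome = chr,
          position = profile$position[pos_idx],
          lod = lod[i],
          ci_lo = profile$position[sel[lo]],
          ci_hi = profile$position[sel[hi]],
          effect = slope / 2,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(trait = character(), chromosome = character(),
                      position = numeric(), lod = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(),
                      effect = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$trait, out$chromosome, out$position), , drop = FALSE]
}

#' Phenotypic variance explained by a set of QTL
#'
#' Joint multiple regression of the phenotype on P(BB) at every hit peak;
#' returns the model R^2 (fraction; multiply by 100 for percent). Duplicate
#' peak positions are deduplicated with a warning.
#'
#' @inheritParams find_peaks
#' @param hits data.frame of peaks (needs columns chromosome, position), e.g.
#'   one trait's rows from [find_peaks()].
#' @param phenotype Numeric vector named by RIL.
#' @return R^2 in [0, 1]; 0 if `hits` is empty.
#' @export
variance_explained <- function(genoprobs, phenotype, hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(0)
  grid <- attr(genoprobs, "grid")
  pbb <- pbb_matrix(genoprobs)
  key <- paste(hits$chromosome, hits$position)
  if (anyDuplicated(key)) {
    warning("duplicate peak positions collapsed before fitting", call. = FALSE)
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  idx <- vapply(seq_len(nrow(hits)), function(i) {
    j <- which(grid$chromosome == as.character(hits$chromosome[i]) &
                 abs(grid$position - hits$position[i]) < 1e-8)
    if (length(j) == 0L) stop("hit position not on the scan grid", call. = FALSE)
    j[1L]
  }, integer(1))
  y <- phenotype
  if (!is.null(names(y))) y <- y[rownames(pbb)]
  keep <- is.finite(y)
  X <- pbb[keep, idx, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X), y[keep])
  1 - sum(fit$residuals^2) / sum((y[keep] - mean(y[keep]))^2)
}
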