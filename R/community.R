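# Ecological screens linking rate constants to community structure:
# rarefaction, alpha diversity, Spearman OTU screening with
# Benjamini-Hochberg control, transcript-per-million normalisation and CA
# class/clade expression-rate correlations.

#' Rarefy an OTU count table
#'
#' Subsamples every retained site without replacement to exactly `depth`
#' reads (via `vegan::rrarefy`); sites with fewer reads than `depth` are
#' dropped with a warning. Reproducible given `seed`.
#'
#' @param counts sites x OTUs non-negative integer matrix with dimnames.
#' @param depth Target depth (reads per site).
#' @param seed Integer seed.
#' @return Rarefied count matrix (possibly with fewer rows).
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), depth > 0, depth == round(depth))
  totals <- rowSums(counts)
  low <- totals < depth
  if (any(low)) {
    warning(sprintf("dropped %d site(s) below rarefaction depth %d: %s",
                    sum(low), depth,
                    paste(rownames(counts)[low], collapse = ", ")))
    counts <- counts[!low, , drop = FALSE]
  }
  if (!nrow(counts)) stop("no site at or above the rarefaction depth")
  withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    # vegan guesses tables whose smallest nonzero count exceeds 1 are not
    # raw counts; ours are, so muffle that specific advisory
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
}

#' Per-site richness and Shannon diversity
#'
#' Observed OTUs (count of nonzero OTUs) and the Shannon index
#' `H' = -sum(p * log(p))` over nonzero proportions, in natural log by
#' default.
#'
#' @param counts sites x OTUs count (or proportion) matrix.
#' @param base Logarithm base for Shannon (default `exp(1)`, nats).
#' @return data.frame with `site`, `observed_otus`, `shannon`.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0)) stop("empty site (all-zero row)")
  data.frame(site = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             observed_otus = rowSums(counts > 0),
             shannon = vegan::diversity(counts, index = "shannon",
                                        base = base),
             row.names = NULL)
}

# Spearman p-value: exact null distribution for small n without ties,
# t approximation otherwise.
spearman_p <- function(rho, n, x = NULL, y = NULL) {
  if (n < 10 && !is.null(x) && !anyDuplicated(x) && !anyDuplicated(y)) {
    return(suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value))
  }
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Spearman OTU-variable screen with FDR control
#'
#' Rank-correlates every OTU column against a per-site variable (average
#' ranks for ties), adjusts p-values across all tested OTUs by
#' Benjamini-Hochberg, and reports hits satisfying `|rho| > rho_min` and
#' `q < q_max`.
#'
#' @param rel_abund sites x OTUs numeric matrix (relative abundances of the
#'   rarefied table by default in the pipeline).
#' @param variable Per-site scalar (e.g. a catalyzed rate constant).
#' @param rho_min,q_max Screen thresholds.
#' @return data.frame with `otu`, `rho`, `p`, `q`, `hit`; constant OTU
#'   columns are excluded and listed in the `"excluded"` attribute.
#' @export
spearman_screen <- function(rel_abund, variable, rho_min = 0.5,
                            q_max = 0.01) {
  m <- as.matrix(rel_abund)
  stopifnot(nrow(m) >= 4, length(variable) == nrow(m),
            all(is.finite(variable)))
  if (stats::sd(variable) == 0) stop("variable is constant; no ranking possible")
  if (is.null(colnames(m))) colnames(m) <- paste0("OTU_", seq_len(ncol(m)))
  const <- apply(m, 2, function(col) stats::sd(col) == 0)
  excluded <- colnames(m)[const]
  m <- m[, !const, drop = FALSE]
  if (!ncol(m)) stop("all OTU columns are constant")
  n <- nrow(m)
  rv <- rank(variable)
  R <- apply(m, 2, rank)
  rho <- as.vector(stats::cor(R, rv))
  p <- vapply(seq_len(ncol(m)), function(j) {
    spearman_p(rho[j], n, x = m[, j], y = variable)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(otu = colnames(m), rho = rho, p = p, q = q,
                    hit = abs(rho) > rho_min & q < q_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Transcripts-per-million normalisation
#'
#' `tpm_ij = (count_ij / length_j) / sum_j(count_ij / length_j) * 1e6`.
#' Every sample row with any reads sums to 1e6; all-zero samples yield a
#' zero row and are listed in the `"zero_samples"` attribute.
#'
#' @param counts samples x genes non-negative matrix.
#' @param gene_length Gene lengths in bp (one per column, > 0).
#' @return samples x genes tpm matrix.
#' @export
tpm_normalize <- function(counts, gene_length) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_length) == ncol(counts), all(gene_length > 0),
            all(counts >= 0))
  rate <- sweep(counts, 2, gene_length, "/")
  tot <- rowSums(rate)
  zero <- tot == 0
  tot[zero] <- 1
  tpm <- rate / tot * 1e6
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s) left as zero rows", sum(zero)))
  }
  attr(tpm, "zero_samples") <- rownames(counts)[zero]
  tpm
}

#' Pearson correlation of grouped CA expression with reaction rates
#'
#' Sums tpm within each gene group (CA class, clade or cluster) per sample
#' and correlates the totals with per-sample catalyzed rate constants.
#' Genes from small genomes (limited CA recovery) are expected to be
#' filtered out before this call.
#'
#' @param tpm samples x genes tpm matrix.
#' @param groups Factor or character vector of length `ncol(tpm)` assigning
#'   each gene to a group.
#' @param rates Per-sample rate constants (length `nrow(tpm)`).
#' @param min_samples Minimum paired samples required per group.
#' @return data.frame with `group`, `r`, `p`, `n`.
#' @export
class_rate_correlation <- function(tpm, groups, rates, min_samples = 4) {
  tpm <- as.matrix(tpm)
  stopifnot(length(groups) == ncol(tpm), length(rates) == nrow(tpm))
  ok <- is.finite(rates)
  out <- lapply(split(seq_len(ncol(tpm)), groups), function(idx) {
    total <- rowSums(tpm[, idx, drop = FALSE])
    keep <- ok & is.finite(total)
    g <- as.character(groups[idx[1]])
    if (sum(keep) < min_samples) {
      stop(sprintf("group '%s' has fewer than %d paired samples",
                   g, min_samples))
    }
    if (stats::sd(total[keep]) == 0) {
      return(data.frame(group = g, r = NA_real_, p = NA_real_,
                        n = sum(keep)))
    }
    ct <- stats::cor.test(total[keep], rates[keep], method = "pearson")
    data.frame(group = g, r = unname(ct$estimate), p = ct$p.value,
               n = sum(keep))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
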