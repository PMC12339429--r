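#' Configuration for the paired GWAS summary-statistics simulator
#'
#' Describes a seeded two-sample MR scenario with known truth: per-SNP
#' exposure effects drawn in a magnitude range with random sign, outcome
#' effects generated as
#' `beta_out = beta_causal * beta_exp_true + pleiotropy + heterogeneity +
#' noise`, and observation noise at the configured standard errors.  The
#' defaults emulate a small protein-GWAS exposure panel against a large
#' biobank outcome: nine instruments, a causal log-OR of 0.347
#' (odds ratio about 1.41), exposure effect magnitudes 0.10-0.45 with SE
#' 0.03 (exposure sample 3,301), and outcome SE 0.15 (outcome sample
#' 178,726).
#'
#' @param k_snps Number of instruments.
#' @param beta_causal True causal effect (log-OR scale).
#' @param exposure_beta_range Magnitude range of true exposure effects.
#' @param se_exp,se_out Standard-error scales of the two panels.
#' @param n_exp,n_out Reported sample sizes.
#' @param pleiotropy List: `type` in `none`/`balanced`/`directional`,
#'   `mean` (directional only), `sd`.
#' @param heterogeneity_sd SD of extra per-SNP effect heterogeneity.
#' @param palindromic_frac Fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs with intermediate allele frequency, to exercise
#'   harmonization.
#' @param ld_blocks Optional list for [simulate_ld_panel()]: `sizes`
#'   (integer vector of block sizes), `r2` (within-block r-squared),
#'   `spacing_kb` (between consecutive SNPs of a block), `gap_kb`
#'   (between blocks).
#' @param seed Integer seed.
#' @return A list of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(k_snps = 9, beta_causal = 0.347,
                            exposure_beta_range = c(0.10, 0.45),
                            se_exp = 0.03, se_out = 0.15,
                            n_exp = 3301, n_out = 178726,
                            pleiotropy = list(type = "none", mean = 0, sd = 0),
                            heterogeneity_sd = 0, palindromic_frac = 0,
                            ld_blocks = NULL, seed = 1) {
  stopifnot(k_snps >= 1, se_exp > 0, se_out > 0, heterogeneity_sd >= 0,
            palindromic_frac >= 0, palindromic_frac <= 1,
            length(exposure_beta_range) == 2,
            exposure_beta_range[1] > 0,
            diff(exposure_beta_range) >= 0)
  pleiotropy$type <- match.arg(pleiotropy$type %||% "none",
                               c("none", "balanced", "directional"))
  pleiotropy$mean <- pleiotropy$mean %||% 0
  pleiotropy$sd <- pleiotropy$sd %||% 0
  if (pleiotropy$sd < 0) stop_stage("gwas_sim_config", "pleiotropy sd < 0")
  structure(list(k_snps = as.integer(k_snps), beta_causal = beta_causal,
                 exposure_beta_range = exposure_beta_range,
                 se_exp = se_exp, se_out = se_out,
                 n_exp = as.integer(n_exp), n_out = as.integer(n_out),
                 pleiotropy = pleiotropy,
                 heterogeneity_sd = heterogeneity_sd,
                 palindromic_frac = palindromic_frac,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "gwas_sim_config")
}

#' Read a `gwas_sim_config` from YAML
#' @param path YAML file whose keys match [gwas_sim_config()] arguments.
#' @return A `gwas_sim_config`.
#' @export
read_gwas_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$exposure_beta_range))
    cfg$exposure_beta_range <- unlist(cfg$exposure_beta_range)
  do.call(gwas_sim_config, cfg)
}

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"),
                             c("T", "C"), c("G", "A"), c("C", "A"),
                             c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"),
                          c("G", "C"))

#' Simulate a paired exposure/outcome GWAS summary panel
#'
#' Draws true exposure effects uniformly in the configured magnitude range
#' with random signs, observes them with normal noise at `se_exp`, and
#' generates outcome associations under the linear causal model with the
#' configured pleiotropy (balanced: zero-mean; directional: nonzero mean)
#' and heterogeneity.  Alleles, positions and allele frequencies are drawn
#' so that `palindromic_frac` of SNPs are strand-ambiguous at intermediate
#' frequency.  p-values are the two-sided normal tails of `beta/se`.  The
#' truth record retains every latent quantity.
#'
#' @param cfg A [gwas_sim_config()].
#' @return A list: `exposure` and `outcome` (`gwas_sumstats` data frames)
#'   and `truth` (list with `beta_exp_true`, `pleiotropy`,
#'   `heterogeneity`, `beta_causal`, `seed`).
#' @export
simulate_gwas_pair <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  with_seed(cfg$seed, {
    k <- cfg$k_snps
    rg <- cfg$exposure_beta_range
    # latent effects are defined in the exposure-increasing orientation
    # (pleiotropy "directional" means directional relative to that frame);
    # a random per-SNP allele flip is applied afterwards, as allele coding
    # in real summary statistics is arbitrary
    bx_pos <- stats::runif(k, rg[1], rg[2])
    pl <- switch(cfg$pleiotropy$type,
                 none = rep(0, k),
                 balanced = stats::rnorm(k, 0, cfg$pleiotropy$sd),
                 directional = stats::rnorm(k, cfg$pleiotropy$mean,
                                            cfg$pleiotropy$sd))
    het <- if (cfg$heterogeneity_sd > 0)
      stats::rnorm(k, 0, cfg$heterogeneity_sd) else rep(0, k)
    flip <- sample(c(-1, 1), k, replace = TRUE)
    bx_true <- flip * bx_pos
    by_true <- flip * (cfg$beta_causal * bx_pos + pl + het)

    bx <- bx_true + stats::rnorm(k, 0, cfg$se_exp)
    by <- by_true + stats::rnorm(k, 0, cfg$se_out)

    pal <- stats::runif(k) < cfg$palindromic_frac
    pairs <- vector("list", k)
    pairs[pal] <- PALINDROMIC_PAIRS[sample.int(4, sum(pal), replace = TRUE)]
    pairs[!pal] <- NONPALINDROMIC_PAIRS[sample.int(8, sum(!pal),
                                                   replace = TRUE)]
    ea <- vapply(pairs, `[`, character(1), 1)
    oa <- vapply(pairs, `[`, character(1), 2)
    eaf <- ifelse(pal, stats::runif(k, 0.43, 0.57), stats::runif(k, 0.05, 0.95))

    chrom <- as.character(sample.int(22, k, replace = TRUE))
    pos <- sample.int(2e8, k)
    ids <- sprintf("rs%06d", sample.int(999999, k))

    exposure <- as_gwas_sumstats(data.frame(
      snp_id = ids, chrom = chrom, pos = pos, effect_allele = ea,
      other_allele = oa, eaf = eaf, beta = bx, se = rep(cfg$se_exp, k),
      p = 2 * stats::pnorm(-abs(bx / cfg$se_exp)), n = cfg$n_exp,
      stringsAsFactors = FALSE))
    outcome <- as_gwas_sumstats(data.frame(
      snp_id = ids, chrom = chrom, pos = pos, effect_allele = ea,
      other_allele = oa, eaf = eaf, beta = by, se = rep(cfg$se_out, k),
      p = 2 * stats::pnorm(-abs(by / cfg$se_out)), n = cfg$n_out,
      stringsAsFactors = FALSE))
    truth <- list(beta_causal = cfg$beta_causal, beta_exp_true = bx_true,
                  pleiotropy = pl, heterogeneity = het, allele_flip = flip,
                  seed = cfg$seed)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate a block-structured LD panel
#'
#' Builds an exposure panel whose SNPs fall into LD blocks: within-block
#' pairwise r-squared at the configured level, zero between blocks, with
#' genomic positions spaced so blocks land inside or outside a clumping
#' window as configured.  All SNPs are placed on one chromosome with
#' p-values increasing in panel order, so clumping outcomes are easy to
#' reason about.
#'
#' @param cfg A [gwas_sim_config()] with `ld_blocks` set.
#' @return A list: `snps` (a `gwas_sumstats` data frame), `ld` (long-form
#'   r-squared table) and `blocks` (block index per SNP).
#' @export
simulate_ld_panel <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  lb <- cfg$ld_blocks
  if (is.null(lb)) stop_stage("simulate_ld_panel", "ld_blocks not configured")
  sizes <- as.integer(lb$sizes)
  r2 <- lb$r2 %||% 0.9
  spacing_kb <- lb$spacing_kb %||% 5
  gap_kb <- lb$gap_kb %||% 20000
  stopifnot(all(sizes >= 1), r2 >= 0, r2 <= 1)
  with_seed(cfg$seed, {
    k <- sum(sizes)
    block <- rep(seq_along(sizes), sizes)
    pos <- integer(k); cur <- 1e6
    for (i in seq_len(k)) {
      if (i > 1) cur <- cur + if (block[i] != block[i - 1])
        gap_kb * 1000 else spacing_kb * 1000
      pos[i] <- cur
    }
    beta <- stats::runif(k, cfg$exposure_beta_range[1],
                         cfg$exposure_beta_range[2])
    p <- sort(stats::runif(k, 1e-10, 4.9e-6))
    snps <- as_gwas_sumstats(data.frame(
      snp_id = sprintf("blk%d_snp%d", block, stats::ave(block, block,
                                                        FUN = seq_along)),
      chrom = "1", pos = pos, effect_allele = "A", other_allele = "G",
      eaf = stats::runif(k, 0.1, 0.9), beta = beta,
      se = rep(cfg$se_exp, k), p = p, n = cfg$n_exp,
      stringsAsFactors = FALSE))
    pairs <- which(outer(block, block, `==`) & upper.tri(diag(k)),
                   arr.ind = TRUE)
    ld <- data.frame(snp_i = snps$snp_id[pairs[, 1]],
                     snp_j = snps$snp_id[pairs[, 2]],
                     r2 = rep(r2, nrow(pairs)), stringsAsFactors = FALSE)
    list(snps = snps, ld = ld, blocks = block)
  })
}
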