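#' Simulation configuration for case-control disease data
#'
#' Bundles the parameters of the synthetic study design: a haplotype pool
#' emulating a resequenced region, causal-variant placement, and a
#' population-attributable-risk (PAR) penetrance model.  Defaults follow
#' the study design the package's calibration experiments use: a pool of
#' 10,000 haplotypes over a 20 kb region with ~330 segregating sites,
#' 20 causal variants clustered within 6 kb, baseline penetrance 1%, and
#' 500 cases + 500 controls.
#'
#' @param H pool size (number of haplotypes).
#' @param region_length region length in bp.
#' @param n_sites number of segregating sites.
#' @param common_frac fraction of sites drawn from the common-frequency
#'   stratum (MAF in (0.05, 0.5)), included so the downstream MAF filter is
#'   exercised; the rest are rare, with pool frequency drawn from a
#'   1/x-shaped spectrum on [1/H, 0.05].
#' @param n_causal number of causal variants.
#' @param clustered logical; if `TRUE` causal variants are placed inside a
#'   random window of `cluster_span` bp, otherwise approximately equally
#'   spaced across the region.
#' @param cluster_span width of the causal cluster in bp (6000 for 20
#'   causal variants; 3000 is the matching choice for 10).
#' @param n_protective,n_deleterious direction mix; must sum to `n_causal`.
#' @param par per-causal-variant population attributable risk in [0, 1);
#'   0 gives the null model.
#' @param f0 baseline penetrance (risk with no causal minor alleles).
#' @param n_cases,n_controls sampling quotas.
#' @param ld_founders optional integer < `H`: build the pool as block-copy
#'   mosaics of this many founder haplotypes, inducing local linkage
#'   disequilibrium.  `NULL` (default) samples alleles independently across
#'   sites, the low-LD regime typical of rare variants.
#' @param draw_budget maximum number of subjects drawn before sampling
#'   aborts.
#' @param seed optional integer seed used by [simulate_case_control()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(H = 10000, region_length = 20000, n_sites = 330,
                       common_frac = 0.15,
                       n_causal = 20, clustered = TRUE, cluster_span = 6000,
                       n_protective = 10, n_deleterious = 10,
                       par = 0, f0 = 0.01,
                       n_cases = 500, n_controls = 500,
                       ld_founders = NULL, draw_budget = 2e6, seed = NULL) {
  cfg <- list(H = as.integer(H), region_length = as.integer(region_length),
              n_sites = as.integer(n_sites), common_frac = common_frac,
              n_causal = as.integer(n_causal), clustered = isTRUE(clustered),
              cluster_span = as.integer(cluster_span),
              n_protective = as.integer(n_protective),
              n_deleterious = as.integer(n_deleterious),
              par = par, f0 = f0,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              ld_founders = if (is.null(ld_founders)) NULL else as.integer(ld_founders),
              draw_budget = draw_budget, seed = seed)
  if (cfg$H < 2L) stop("pool size H must be >= 2")
  if (cfg$n_sites > cfg$region_length)
    stop("cannot place more sites than base pairs in the region")
  if (cfg$n_causal != cfg$n_protective + cfg$n_deleterious)
    stop("n_causal must equal n_protective + n_deleterious")
  if (cfg$n_causal > cfg$n_sites) stop("n_causal cannot exceed n_sites")
  if (cfg$par < 0 || cfg$par >= 1) stop("par must be in [0, 1)")
  if (cfg$f0 <= 0 || cfg$f0 >= 1) stop("f0 must be in (0, 1)")
  if (cfg$cluster_span > cfg$region_length)
    stop("cluster_span cannot exceed region_length")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a haplotype pool
#'
#' Builds the synthetic population from which case-control samples are
#' drawn: `H` binary haplotypes over `n_sites` sites placed uniformly at
#' random in the region.  Per-site pool frequencies are drawn from a
#' rare-skewed spectrum with density proportional to 1/x on
#' [1/H, 0.05] (log-uniform), matching the excess of very rare alleles in
#' resequencing data, plus a `common_frac` fraction of common sites with
#' frequency uniform in (0.05, 0.5).  Alleles are sampled independently
#' across sites (low LD) unless `ld_founders` is set, in which case each
#' haplotype is a block-copy mosaic of a smaller founder set.  Every site
#' is guaranteed polymorphic in the pool.
#'
#' @param config a [sim_config()].
#' @return An object of class `haplotype_pool`: list with `haplotypes`
#'   (H x S binary matrix), `positions`, `freqs` (the drawn spectrum
#'   frequencies) and `region_length`.
#' @export
build_haplotype_pool <- function(config) {
  H <- config$H; S <- config$n_sites; L <- config$region_length
  positions <- sort(sample.int(L, S))
  n_common <- stats::rbinom(1L, S, config$common_frac)
  is_common <- rep(FALSE, S)
  if (n_common > 0L) is_common[sample.int(S, n_common)] <- TRUE
  freqs <- numeric(S)
  # 1/x spectrum on [1/H, 0.05] via inverse-CDF (log-uniform)
  lo <- log(1 / H); hi <- log(0.05)
  freqs[!is_common] <- exp(stats::runif(S - n_common, lo, hi))
  freqs[is_common] <- stats::runif(n_common, 0.05, 0.5)

  draw_col <- function(f) {
    x <- stats::rbinom(H, 1L, f)
    tries <- 0L
    while ((s <- sum(x)) == 0L || s == H) {  # enforce polymorphism
      x <- stats::rbinom(H, 1L, f)
      tries <- tries + 1L
      if (tries > 1000L) { x <- integer(H); x[sample.int(H, 1L)] <- 1L; break }
    }
    x
  }

  if (is.null(config$ld_founders)) {
    hap <- matrix(stats::rbinom(H * S, 1L, rep(freqs, each = H)), H, S)
    redo <- which(colSums(hap) == 0L | colSums(hap) == H)
    for (j in redo) hap[, j] <- draw_col(freqs[j])
  } else {
    Fo <- config$ld_founders
    founders <- matrix(stats::rbinom(Fo * S, 1L, rep(freqs, each = Fo)), Fo, S)
    hap <- matrix(0L, H, S)
    for (h in seq_len(H)) {
      # mosaic of founder segments with ~3 breakpoints across the region
      nb <- stats::rpois(1L, 3L)
      bps <- sort(unique(c(0L, sample.int(S - 1L, min(nb, S - 1L)), S)))
      for (k in seq_len(length(bps) - 1L)) {
        seg <- (bps[k] + 1L):bps[k + 1L]
        hap[h, seg] <- founders[sample.int(Fo, 1L), seg]
      }
    }
    redo <- which(colSums(hap) == 0L | colSums(hap) == H)
    for (j in redo) hap[, j] <- draw_col(freqs[j])
  }

  structure(list(haplotypes = hap, positions = positions, freqs = freqs,
                 region_length = L),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d sites over %d bp (%d rare)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$region_length,
              sum(colMeans(x$haplotypes) <= 0.05)))
  invisible(x)
}

#' Choose causal sites and their effect directions
#'
#' Selects `n_causal` rare sites (pool frequency <= 0.05) either clustered
#' -- all inside a randomly placed window of `cluster_span` bp -- or
#' non-clustered -- approximately equally spaced across the region, by
#' greedy assignment of the rare site nearest each point of an ideal
#' equally-spaced grid.  Direction labels (`n_protective` protective, the
#' rest deleterious) are assigned uniformly at random among the chosen
#' sites.
#'
#' @param pool a [build_haplotype_pool()] result.
#' @param config a [sim_config()].
#' @return List with `indices` (sorted site indices into the pool) and
#'   `directions` (character, "protective"/"deleterious", aligned).
#' @export
select_causal_sites <- function(pool, config) {
  freq <- colMeans(pool$haplotypes)
  rare <- which(freq <= 0.05)
  if (length(rare) < config$n_causal)
    stop("not enough rare sites in the pool to place causal variants")
  pos <- pool$positions

  if (config$clustered) {
    span <- config$cluster_span
    picked <- NULL
    for (try in seq_len(100L)) {
      start <- stats::runif(1L, 1, max(1, pool$region_length - span))
      inside <- rare[pos[rare] >= start & pos[rare] <= start + span]
      if (length(inside) >= config$n_causal) {
        picked <- sort(sample(inside, config$n_causal))
        break
      }
    }
    if (is.null(picked))
      stop("no window of ", span, " bp held ", config$n_causal,
           " rare sites after 100 tries")
  } else {
    grid <- seq(pool$region_length / (2 * config$n_causal),
                pool$region_length * (1 - 1 / (2 * config$n_causal)),
                length.out = config$n_causal)
    avail <- rare
    picked <- integer(0)
    for (g in grid) {
      i <- avail[which.min(abs(pos[avail] - g))]
      picked <- c(picked, i)
      avail <- setdiff(avail, i)
    }
    picked <- sort(picked)
  }

  dirs <- rep("deleterious", config$n_causal)
  if (config$n_protective > 0L)
    dirs[sample.int(config$n_causal, config$n_protective)] <- "protective"
  list(indices = picked, directions = dirs)
}

#' Convert population attributable risk to genotype relative risk
#'
#' Given a causal variant's PAR and MAF, its per-allele genotype relative
#' risk is \eqn{GRR = PAR / (MAF (1 - PAR)) + 1} for a deleterious variant;
#' a protective variant gets the reciprocal.  At PAR = 0 both directions
#' give GRR = 1 (the null).  Note the asymmetry: on the odds-ratio
#' magnitude scale a deleterious variant's effect exceeds a protective
#' variant's at the same PAR and MAF.
#'
#' @param par population attributable risk in [0, 1); vectorised.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param protective logical (vectorised).
#' @return Positive GRR value(s).
#' @export
par_to_grr <- function(par, maf, protective = FALSE) {
  if (any(par < 0) || any(par >= 1)) stop("par must be in [0, 1)")
  if (any(maf <= 0) || any(maf > 0.5)) stop("maf must be in (0, 0.5]")
  grr <- par / (maf * (1 - par)) + 1
  ifelse(protective, 1 / grr, grr)
}

#' Multiplicative penetrance model
#'
#' Disease risk of a subject given minor-allele counts at the causal sites:
#' \eqn{risk = f_0 \prod_j GRR_j^{g_j}}, capped at 1, with \eqn{f_0} the
#' baseline penetrance and \eqn{g_j \in \{0, 1, 2\}} the subject's
#' minor-allele count at causal site j.
#'
#' @param g vector (or subjects-by-causal matrix) of minor-allele counts.
#' @param grrs per-causal-site GRR, aligned to the columns of `g`.
#' @param f0 baseline penetrance.
#' @return Risk probability (vector if `g` is a matrix).
#' @export
penetrance <- function(g, grrs, f0) {
  if (is.matrix(g)) {
    if (ncol(g) != length(grrs)) stop("g and grrs are not aligned")
    pmin(f0 * exp(g %*% log(grrs))[, 1L], 1)
  } else {
    if (length(g) != length(grrs)) stop("g and grrs are not aligned")
    min(f0 * prod(grrs ^ g), 1)
  }
}

#' Sample a case-control panel from a haplotype pool
#'
#' Draws subjects by pairing two haplotypes sampled with replacement from
#' the pool, assigns disease status by a Bernoulli draw at the subject's
#' penetrance, and keeps drawing until both the case and control quotas are
#' filled (surplus subjects of an already-filled class are discarded).
#' Each causal site's GRR is computed from its pool frequency -- PAR is a
#' population quantity -- via [par_to_grr()].  The emitted panel covers all
#' sites, common ones included; [maf_filter()] removes those downstream.
#'
#' @param pool a [build_haplotype_pool()] result.
#' @param causal a [select_causal_sites()] result.
#' @param config a [sim_config()].
#' @return List with `panel` ([genotype_panel()]), `pheno`
#'   ([phenotype_vector()]), and `truth` (causal indices, positions,
#'   directions, GRRs, par) for power bookkeeping.
#' @export
sample_case_control <- function(pool, causal, config) {
  H <- nrow(pool$haplotypes)
  maf_pool <- colMeans(pool$haplotypes)[causal$indices]
  grrs <- par_to_grr(config$par, maf_pool,
                     protective = causal$directions == "protective")
  log_grr <- log(grrs)
  hap_causal <- pool$haplotypes[, causal$indices, drop = FALSE]
  storage.mode(hap_causal) <- "double"

  need_case <- config$n_cases
  need_ctrl <- config$n_controls
  kept_h1 <- integer(0); kept_h2 <- integer(0); kept_status <- integer(0)
  drawn <- 0L
  while (need_case > 0L || need_ctrl > 0L) {
    batch <- min(20000L, max(2000L,
      as.integer(ceiling(need_case / config$f0 + need_ctrl) * 1.2)))
    if (drawn + batch > config$draw_budget) {
      if (drawn >= config$draw_budget)
        stop("draw budget exhausted before filling case/control quotas")
      batch <- as.integer(config$draw_budget - drawn)
    }
    drawn <- drawn + batch
    h1 <- sample.int(H, batch, replace = TRUE)
    h2 <- sample.int(H, batch, replace = TRUE)
    g <- hap_causal[h1, , drop = FALSE] + hap_causal[h2, , drop = FALSE]
    risk <- pmin(config$f0 * exp(g %*% log_grr)[, 1L], 1)
    status <- stats::rbinom(batch, 1L, risk)
    # enforce quotas in draw order; surplus of a filled class is discarded
    cum_case <- cumsum(status == 1L)
    cum_ctrl <- cumsum(status == 0L)
    take <- (status == 1L & cum_case <= need_case) |
            (status == 0L & cum_ctrl <= need_ctrl)
    kept_h1 <- c(kept_h1, h1[take])
    kept_h2 <- c(kept_h2, h2[take])
    kept_status <- c(kept_status, status[take])
    need_case <- config$n_cases - sum(kept_status == 1L)
    need_ctrl <- config$n_controls - sum(kept_status == 0L)
  }

  counts <- pool$haplotypes[kept_h1, , drop = FALSE] +
            pool$haplotypes[kept_h2, , drop = FALSE]
  ids <- paste0("S", seq_along(kept_status))
  panel <- genotype_panel(counts, pool$positions, subject_ids = ids)
  pheno <- phenotype_vector(kept_status, subject_ids = ids)
  list(panel = panel, pheno = pheno,
       truth = list(causal_indices = causal$indices,
                    causal_positions = pool$positions[causal$indices],
                    directions = causal$directions,
                    grrs = grrs, par = config$par))
}

#' One-call simulation of a case-control dataset
#'
#' Convenience wrapper: builds a pool, places causal variants, and samples
#' a case-control panel.  If `config$seed` is set the whole draw is
#' reproducible.
#'
#' @param config a [sim_config()].
#' @return As [sample_case_control()].
#' @export
simulate_case_control <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pool <- build_haplotype_pool(config)
  causal <- select_causal_sites(pool, config)
  sample_case_control(pool, causal, config)
}
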