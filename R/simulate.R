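# Retrospective case-control simulation with latent pathologic states.
# Sampling is exact: the conditional law of (cell, d_true) given clinical
# status is enumerated over the finite covariate support and subjects drawn
# by categorical sampling, so the case/control counts are exact by design.

# Cheap deterministic hash of a serialized object (no external digest
# dependency); used only for reproducibility bookkeeping.
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

derive_seed <- function(seed, replicate_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(replicate_index) * 69621)
             %% 2147483647)
}

#' Simulate one retrospective case-control dataset
#'
#' Draws exactly `n_cases` clinical cases and `n_controls` clinical controls
#' from the conditional laws of `(covariate cell, true state)` given clinical
#' status, computed exactly from [cell_probabilities()].  The latent true
#' state is retained in the output (column `d_true`, coded `0` healthy, `1`
#' disease of interest, `2` nuisance state) so that contamination rates can
#' be verified; estimation routines must ignore it.
#'
#' @param model A [disease_model()].
#' @param cov A [covariate_distribution()].
#' @param design A [study_design()]; the per-replicate RNG state is derived
#'   deterministically from `(design$seed, replicate_index)` (this function
#'   sets the RNG seed).
#' @param replicate_index Replicate number, `1 .. design$replicates`.
#' @return Data frame with columns `dcl`, `d_true`, `g`, `x`, `z1`, ... and
#'   attribute `meta` (seed, derived seed, replicate, counts, model hash).
#' @examples
#' m <- disease_model("trinomial", B = c(-1, -0.69, 1.3, 1.099),
#'                    B_star = c(-1.7, 0, 0.5, 0))
#' cv <- covariate_distribution(genotype_model(0.10), 0.14)
#' d <- simulate_dataset(m, cv, study_design(100, 100, seed = 7))
#' table(d$dcl, d$d_true)
#' @export
simulate_dataset <- function(model, cov, design, replicate_index = 1L) {
  stopifnot(inherits(design, "gxe_design"))
  if (replicate_index < 1L || replicate_index > design$replicates) {
    stop("`replicate_index` must lie in 1..design$replicates", call. = FALSE)
  }
  cp <- cell_probabilities(model, cov)
  zcols <- grep("^z[0-9]+$", names(cp), value = TRUE)
  # stack (cell, d_true) categories: d_true in {0, 1, 2}
  cat_tab <- rbind(
    data.frame(cp[c("g", "x", zcols)], d_true = 0L, dcl = 0L,
               p = cp$mass * cp$p_d0),
    data.frame(cp[c("g", "x", zcols)], d_true = 1L, dcl = 1L,
               p = cp$mass * cp$p_d1),
    data.frame(cp[c("g", "x", zcols)], d_true = 2L, dcl = 1L,
               p = cp$mass * cp$p_d1star))
  p1 <- sum(cat_tab$p[cat_tab$dcl == 1L])
  if (p1 <= 0 || p1 >= 1) {
    stop("zero-mass clinical class; cannot sample cases and controls",
         call. = FALSE)
  }
  rep_seed <- derive_seed(design$seed, replicate_index)
  set.seed(rep_seed)
  draw <- function(pool, n) {
    idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$p)
    pool[idx, c("dcl", "d_true", "g", "x", zcols)]
  }
  out <- rbind(draw(cat_tab[cat_tab$dcl == 1L, ], design$n_cases),
               draw(cat_tab[cat_tab$dcl == 0L, ], design$n_controls))
  rownames(out) <- NULL
  attr(out, "meta") <- list(seed = design$seed, rep_seed = rep_seed,
                            replicate_index = as.integer(replicate_index),
                            n0 = design$n_controls, n1 = design$n_cases,
                            config_hash = fnv1a_hash(list(model, cov)))
  out
}

#' Write a simulated dataset as CSV with a JSON sidecar
#'
#' The CSV has header `dcl,d_true,g,x,z1,...` with 0/1 coding (`d_true = 2`
#' is the nuisance state); the sidecar `<path>.meta.json` documents the
#' coding and the reproducibility metadata.
#'
#' @param data A dataset from [simulate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  meta <- attr(data, "meta")
  meta$d_true_coding <- list(`0` = "healthy", `1` = "disease of interest",
                             `2` = "nuisance state (1*)")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic per-SNP screen fixture
#'
#' Generates a synthetic stand-in for a multi-SNP case-control screen: one
#' shared set of clinical outcomes, environment and covariates, plus
#' independent genotype columns, a configurable subset of which carry nonzero
#' `betaG` and/or `betaGxX`.  The base rows `(dcl, x, z)` are drawn from the
#' retrospective law of the all-null template model; each SNP column is then
#' drawn from `pr(g | dcl, x, z)` under that SNP's own model, which is exact
#' for null SNPs and for non-null SNPs reproduces the marginal
#' genotype-outcome association.
#'
#' @param n_snps Number of SNPs.
#' @param cov A [covariate_distribution()].
#' @param design A [study_design()] (its seed drives the whole fixture).
#' @param effect_spec List with `n_nonnull` (count of non-null SNPs, placed
#'   first), `betaG` and `betaGxX` (their effects).
#' @param template A [disease_model()] (either kind) providing the intercept,
#'   environment, covariate effects and contamination or nuisance-state
#'   coefficients; its `betaG`/`betaGxX` are overridden per SNP.  Default:
#'   binary model with `beta0 = -1`, `betaX = 1.3`, null G effects,
#'   `S = (0.36, 0.06)`, zero Z effects.
#' @return List with `base` (data frame `dcl, x, z...`), `genotypes`
#'   (n-by-`n_snps` 0/1 matrix, columns `snp1...`), and `truth` (data frame
#'   `snp_id, betaG, betaGxX, nonnull`, plus the nuisance-state G effects
#'   when the template is trinomial).
#' @export
make_snp_screen_fixture <- function(n_snps, cov, design,
                                    effect_spec = list(n_nonnull = 0,
                                                       betaG = 0.8,
                                                       betaGxX = 0),
                                    template = NULL) {
  stopifnot(n_snps >= 1, inherits(design, "gxe_design"))
  if (is.null(template)) {
    template <- disease_model(
      "binary_with_contamination", B = c(-1, 0, 1.3, 0),
      Z_effects = rep(0, n_covariates(cov)),
      contamination = contamination_spec(0.36, 0.06))
  }
  spec <- utils::modifyList(list(n_nonnull = 0, betaG = 0.8, betaGxX = 0),
                            as.list(effect_spec))
  n_nonnull <- spec$n_nonnull
  stopifnot(n_nonnull <= n_snps)
  truth <- data.frame(
    snp_id = paste0("snp", seq_len(n_snps)),
    betaG = c(rep(spec$betaG, n_nonnull), rep(0, n_snps - n_nonnull)),
    betaGxX = c(rep(spec$betaGxX, n_nonnull), rep(0, n_snps - n_nonnull)),
    nonnull = c(rep(TRUE, n_nonnull), rep(FALSE, n_snps - n_nonnull)))
  if (template$kind == "trinomial") {
    truth$betaG_star <- template$B_star[["betaG_star"]]
    truth$betaGxX_star <- template$B_star[["betaGxX_star"]]
  }

  null_model <- template
  null_model$B[c("betaG", "betaGxX")] <- 0
  base_full <- simulate_dataset(null_model, cov, design, replicate_index = 1L)
  zcols <- grep("^z[0-9]+$", names(base_full), value = TRUE)
  base <- base_full[c("dcl", "x", zcols)]
  n <- nrow(base)

  # pr(g = 1 | dcl, x, z) per SNP model, over the (dcl, x, z) patterns
  set.seed(derive_seed(design$seed, 0L) )
  G <- matrix(0L, n, n_snps, dimnames = list(NULL, truth$snp_id))
  for (s in seq_len(n_snps)) {
    ms <- template
    ms$B["betaG"] <- truth$betaG[s]
    ms$B["betaGxX"] <- truth$betaGxX[s]
    cp <- cell_probabilities(ms, cov)
    # join each subject to its (x, z) pattern for both genotype values
    key_cells <- do.call(paste, c(cp[c("x", zcols)], sep = "/"))
    key_base <- do.call(paste, c(base[c("x", zcols)], sep = "/"))
    pg1 <- numeric(n)
    for (pat in unique(key_base)) {
      i0 <- which(key_cells == pat & cp$g == 0)
      i1 <- which(key_cells == pat & cp$g == 1)
      rows <- key_base == pat
      # pr(g, dcl | x, z) up to the shared pr(x, z) factor
      w1_case <- cp$mass[i1] * cp$p_dcl1[i1]
      w0_case <- cp$mass[i0] * cp$p_dcl1[i0]
      w1_ctrl <- cp$mass[i1] * (1 - cp$p_dcl1[i1])
      w0_ctrl <- cp$mass[i0] * (1 - cp$p_dcl1[i0])
      pg1[rows & base$dcl == 1] <- w1_case / (w1_case + w0_case)
      pg1[rows & base$dcl == 0] <- w1_ctrl / (w1_ctrl + w0_ctrl)
    }
    G[, s] <- rbinom(n, 1L, pg1)
  }
  list(base = base, genotypes = G, truth = truth)
}
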