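#' Configuration for the synthetic two-platform cohort generator
#'
#' Defaults encode the study conditions the generator emulates: a 54-sample
#' lymphoma cohort split into three latent immune subtypes (10 immune-poor,
#' 24 immune-intermediate, 20 immune-rich), 15 gene signatures (13 immune
#' cell types plus CAF and EC), 15 HLA genes (9 class I, 6 class II) with
#' status-dependent down-regulation, planted ligand-receptor pairs driven by
#' the infiltration latent factor, and subtype-linked exponential survival.
#'
#' @param n_samples Cohort size.
#' @param subtype_counts Named integer vector `poor`/`intermediate`/`rich`
#'   summing to `n_samples`.
#' @param n_genes Total number of genes in the counts matrix.
#' @param genes_per_signature Genes per signature set.
#' @param infiltration_effect Log2-scale mean shift of immune signature genes
#'   per unit of the latent infiltration factor (delta).
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param n_hla_class1,n_hla_class2 Number of HLA class I / class II genes.
#' @param hla_down_shift Log2 down-shift applied to HLA genes of a
#'   down-regulated class.
#' @param n_planted_lr_pairs Number of ligand-receptor pairs sharing the
#'   infiltration latent factor.
#' @param lr_loading Loading lambda in (0, 1] of planted pairs on the
#'   infiltration factor; the remainder is independent per-gene noise.
#' @param lr_effect Log2 dynamic range of planted ligand/receptor genes
#'   across the latent factor (4 by default, i.e. a 16-fold swing, as
#'   observed for infiltration-driven chemokine and checkpoint genes).
#' @param background_lr_pairs Number of background ("brain tissue") pairs
#'   whose genes carry no shared factor.
#' @param probes_per_gene Integer range (length 2) of probes per gene in the
#'   microarray view.
#' @param intensity_noise_sd Gaussian noise sd added to probe intensities.
#' @param baseline_hazard_os,baseline_hazard_rfs Exponential event rates per
#'   month for non-rich samples.
#' @param subtype_hr Hazard ratio of the immune-rich subtype versus the rest
#'   (0.3 encodes the more favorable outcome of immune-rich tumors).
#' @param censor_frac Target fraction of samples censored (independent
#'   uniform censoring).
#' @param seed Integer seed; every random draw of the generator flows from it.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 54L,
                          subtype_counts = c(poor = 10L, intermediate = 24L, rich = 20L),
                          n_genes = 2000L,
                          genes_per_signature = 20L,
                          infiltration_effect = 2,
                          nb_dispersion = 0.3,
                          n_hla_class1 = 9L,
                          n_hla_class2 = 6L,
                          hla_down_shift = 1.5,
                          n_planted_lr_pairs = 30L,
                          lr_loading = 0.8,
                          lr_effect = 4,
                          background_lr_pairs = 10L,
                          probes_per_gene = c(1L, 3L),
                          intensity_noise_sd = 0.4,
                          baseline_hazard_os = 0.03,
                          baseline_hazard_rfs = 0.05,
                          subtype_hr = 0.3,
                          censor_frac = 0.3,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              subtype_counts = subtype_counts,
              n_genes = as.integer(n_genes),
              genes_per_signature = as.integer(genes_per_signature),
              infiltration_effect = infiltration_effect,
              nb_dispersion = nb_dispersion,
              n_hla_class1 = as.integer(n_hla_class1),
              n_hla_class2 = as.integer(n_hla_class2),
              hla_down_shift = hla_down_shift,
              n_planted_lr_pairs = as.integer(n_planted_lr_pairs),
              lr_loading = lr_loading,
              lr_effect = lr_effect,
              background_lr_pairs = as.integer(background_lr_pairs),
              probes_per_gene = as.integer(probes_per_gene),
              intensity_noise_sd = intensity_noise_sd,
              baseline_hazard_os = baseline_hazard_os,
              baseline_hazard_rfs = baseline_hazard_rfs,
              subtype_hr = subtype_hr,
              censor_frac = censor_frac,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "CohortConfig")
}

validate_cohort_config <- function(cfg) {
  sc <- cfg$subtype_counts
  if (!all(c("poor", "intermediate", "rich") %in% names(sc))) {
    stop("`subtype_counts` needs entries poor/intermediate/rich", call. = FALSE)
  }
  if (sum(sc) != cfg$n_samples) {
    stop("`subtype_counts` must sum to `n_samples`", call. = FALSE)
  }
  if (any(sc <= 0)) stop("all subtype counts must be positive", call. = FALSE)
  if (!(cfg$lr_loading >= 0 && cfg$lr_loading <= 1)) {
    stop("`lr_loading` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("`nb_dispersion` must be positive", call. = FALSE)
  if (length(cfg$probes_per_gene) != 2L || any(cfg$probes_per_gene < 1L) ||
      cfg$probes_per_gene[1] > cfg$probes_per_gene[2]) {
    stop("`probes_per_gene` must be an increasing range of positive integers", call. = FALSE)
  }
  if (cfg$censor_frac < 0 || cfg$censor_frac >= 1) {
    stop("`censor_frac` must lie in [0, 1)", call. = FALSE)
  }
  n_special <- 15L * cfg$genes_per_signature + cfg$n_hla_class1 + cfg$n_hla_class2 +
    2L * (cfg$n_planted_lr_pairs + cfg$background_lr_pairs)
  if (n_special > cfg$n_genes) {
    stop(sprintf("infeasible config: %d structured genes exceed n_genes = %d",
                 n_special, cfg$n_genes), call. = FALSE)
  }
  invisible(cfg)
}

# Signature names of the emulated collection: 13 immune cell types plus the
# two stromal compartments. The first seven are T-cell signatures used for
# immune subtyping.
synthetic_signature_names <- function() {
  c("Activated_CD8_T_cells", "Activated_CD4_T_cells", "Tregs", "Tfh",
    "Th1", "Th2", "Th17",
    "CD56bright_NK", "CD56dim_NK", "MDSC", "Monocytes", "TAM", "Activated_DC",
    "CAF", "EC")
}

#' T-cell signature names of the synthetic collection
#' @return Character vector (subset of the 13 immune signatures).
#' @export
synthetic_tcell_signatures <- function() synthetic_signature_names()[1:7]

#' Immune (non-stromal) signature names of the synthetic collection
#' @return Character vector of the 13 immune signature names.
#' @export
synthetic_immune_signatures <- function() synthetic_signature_names()[1:13]

#' Generate a synthetic lymphoma cohort with planted immune structure
#'
#' Counts are negative-binomial around per-gene base means (log2 base means
#' uniform on 3-9). Immune signature genes are shifted on the log2 scale by
#' `infiltration_effect` times a latent infiltration factor (1 for rich
#' samples, U(0.3, 0.7) for intermediate, U(0.05, 0.15) for poor); CAF/EC
#' genes follow an independent stromal factor. HLA genes are down-shifted
#' according to a per-sample HLA status drawn so that every immune-rich
#' sample is HLA-normal while poor/intermediate samples mix I-down, II-down
#' and I-and-II-down. Planted ligand-receptor genes load on the infiltration
#' factor with weight `lr_loading`; background pairs carry independent noise
#' only. Survival times are exponential with a reduced hazard
#' (`subtype_hr`) for immune-rich samples and independent uniform censoring
#' calibrated to `censor_frac`.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `expr` (counts `ExpressionMatrix`),
#'   `clinical` (`ClinicalTable`), `lr_db` (`LRDatabase`), `signatures`
#'   (`SignatureCollection`) and `truth` (ground-truth labels: per-sample
#'   subtype, HLA status and infiltration, planted/background pair tables,
#'   HLA gene lists, and signature gene memberships).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  G <- cfg$n_genes
  sc <- cfg$subtype_counts
  subtype <- rep(c("poor", "intermediate", "rich"),
                 times = c(sc[["poor"]], sc[["intermediate"]], sc[["rich"]]))
  subtype <- sample(subtype)            # random order across the cohort
  sample_idv <- sprintf("S%02d", seq_len(n))

  infiltration <- numeric(n)
  infiltration[subtype == "rich"] <- 1
  infiltration[subtype == "intermediate"] <- stats::runif(sum(subtype == "intermediate"), 0.3, 0.7)
  infiltration[subtype == "poor"] <- stats::runif(sum(subtype == "poor"), 0.05, 0.15)
  names(infiltration) <- sample_idv

  gene_ids <- sprintf("G%04d", seq_len(G))
  base <- stats::runif(G, 3, 9)          # log2 base means
  logmu <- matrix(base, G, n, dimnames = list(gene_ids, sample_idv))

  # --- signature genes -------------------------------------------------
  sig_names <- synthetic_signature_names()
  gps <- cfg$genes_per_signature
  sig_genes <- stats::setNames(
    lapply(seq_along(sig_names), function(k) gene_ids[((k - 1) * gps + 1):(k * gps)]),
    sig_names)
  immune_rows <- unlist(sig_genes[synthetic_immune_signatures()], use.names = FALSE)
  stromal_rows <- unlist(sig_genes[c("CAF", "EC")], use.names = FALSE)
  logmu[immune_rows, ] <- logmu[immune_rows, ] +
    cfg$infiltration_effect * rep(infiltration, each = length(immune_rows))
  stromal_factor <- stats::runif(n)
  logmu[stromal_rows, ] <- logmu[stromal_rows, ] +
    cfg$infiltration_effect * rep(stromal_factor, each = length(stromal_rows))

  # --- HLA genes -------------------------------------------------------
  offset <- 15L * gps
  hla1 <- gene_ids[offset + seq_len(cfg$n_hla_class1)]
  hla2 <- gene_ids[offset + cfg$n_hla_class1 + seq_len(cfg$n_hla_class2)]
  hla_status <- rep("normal", n)
  nonrich <- which(subtype != "rich")
  # Mixture over the three down states for non-rich samples, proportional
  # to the observed sizes of the down-regulated clusters (12/12/17).
  hla_status[nonrich] <- sample(c("I_down", "II_down", "I_II_down"),
                                length(nonrich), replace = TRUE,
                                prob = c(12, 12, 17) / 41)
  names(hla_status) <- sample_idv
  down1 <- hla_status %in% c("I_down", "I_II_down")
  down2 <- hla_status %in% c("II_down", "I_II_down")
  logmu[hla1, down1] <- logmu[hla1, down1] - cfg$hla_down_shift
  logmu[hla2, down2] <- logmu[hla2, down2] - cfg$hla_down_shift

  # --- ligand-receptor genes ------------------------------------------
  offset <- offset + cfg$n_hla_class1 + cfg$n_hla_class2
  n_lr <- cfg$n_planted_lr_pairs
  lig <- gene_ids[offset + seq_len(n_lr)]
  rec <- gene_ids[offset + n_lr + seq_len(n_lr)]
  lam <- cfg$lr_loading
  for (i in seq_len(n_lr)) {
    f_l <- lam * infiltration + (1 - lam) * stats::runif(n)
    f_r <- lam * infiltration + (1 - lam) * stats::runif(n)
    logmu[lig[i], ] <- logmu[lig[i], ] + cfg$lr_effect * f_l
    logmu[rec[i], ] <- logmu[rec[i], ] + cfg$lr_effect * f_r
  }
  offset <- offset + 2L * n_lr
  n_bg <- cfg$background_lr_pairs
  bg_lig <- gene_ids[offset + seq_len(n_bg)]
  bg_rec <- gene_ids[offset + n_bg + seq_len(n_bg)]

  mu <- 2^logmu
  counts <- matrix(stats::rnbinom(G * n, size = 1 / cfg$nb_dispersion, mu = mu),
                   G, n, dimnames = dimnames(logmu))
  expr <- expression_matrix(counts, platform = "counts")

  # --- clinical table --------------------------------------------------
  hazard_mult <- ifelse(subtype == "rich", cfg$subtype_hr, 1)
  surv <- function(base_rate) {
    rate <- base_rate * hazard_mult
    t_event <- stats::rexp(n, rate = rate)
    if (cfg$censor_frac > 0) {
      cmax <- censor_horizon(rate, cfg$censor_frac)
      t_cens <- stats::runif(n, 0, cmax)
      list(time = pmin(t_event, t_cens), event = as.numeric(t_event <= t_cens))
    } else {
      list(time = t_event, event = rep(1, n))
    }
  }
  os <- surv(cfg$baseline_hazard_os)
  rfs <- surv(cfg$baseline_hazard_rfs)
  clinical <- clinical_table(data.frame(
    sample_id = sample_idv,
    os_time = os$time, os_event = os$event,
    rfs_time = rfs$time, rfs_event = rfs$event,
    sex = sample(c("M", "F"), n, replace = TRUE),
    mskcc_class = sample(c("1", "2", "3"), n, replace = TRUE),
    stringsAsFactors = FALSE))

  lr_db <- lr_database(c(lig, bg_lig), c(rec, bg_rec),
                       pathways = c(rep("immune_signaling", n_lr),
                                    rep("brain_background", n_bg)),
                       background = c(rep(FALSE, n_lr), rep(TRUE, n_bg)))
  sigs <- signature_collection(sig_genes, provenance = "synthetic TME signatures")

  truth <- list(subtype = stats::setNames(subtype, sample_idv),
                hla_status = hla_status,
                infiltration = infiltration,
                stromal_factor = stats::setNames(stromal_factor, sample_idv),
                planted_pairs = data.frame(ligand = lig, receptor = rec,
                                           stringsAsFactors = FALSE),
                background_pairs = data.frame(ligand = bg_lig, receptor = bg_rec,
                                              stringsAsFactors = FALSE),
                hla_class1_genes = hla1,
                hla_class2_genes = hla2,
                signature_genes = sig_genes,
                tcell_signatures = synthetic_tcell_signatures(),
                immune_signatures = synthetic_immune_signatures())

  list(expr = expr, clinical = clinical, lr_db = lr_db, signatures = sigs,
       truth = truth)
}

# Censoring horizon: C ~ U(0, cmax) with cmax chosen so the expected
# censored fraction over the cohort matches `target`. For T ~ Exp(h),
# P(C < T) = (1 - exp(-h cmax)) / (h cmax).
censor_horizon <- function(rates, target) {
  f <- function(cmax) mean((1 - exp(-rates * cmax)) / (rates * cmax)) - target
  stats::uniroot(f, lower = 1e-6, upper = 1e6)$root
}

#' Derive a probe-level microarray view of a counts cohort
#'
#' Each gene is expanded into 1-3 probes (uniformly within
#' `config$probes_per_gene`). A probe's intensity is its gene's log2(count+1)
#' times a per-probe affinity scale (1 for the first probe of a gene,
#' U(0.8, 1.2) for additional probes) plus Gaussian noise with sd
#' `config$intensity_noise_sd`. The emitted probe map is surjective onto the
#' genes. Randomness derives from `config$seed` (offset so the view's stream
#' is distinct from the cohort's).
#'
#' @param expr A counts-platform `ExpressionMatrix`.
#' @param config The [cohort_config()] used to generate the cohort.
#' @return An intensity-platform `ExpressionMatrix` with a probe map.
#' @export
generate_microarray_view <- function(expr, config = cohort_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$platform != "counts") {
    stop("microarray view requires a counts-platform input", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    genes <- rownames(expr$values)
    lg <- log2(expr$values + 1)
    rng <- config$probes_per_gene
    n_probes <- sample(seq(rng[1], rng[2]), length(genes), replace = TRUE)
    gene_of_probe <- rep(genes, n_probes)
    probe_rank <- sequence(n_probes)
    probe_ids <- paste0(gene_of_probe, "_p", probe_rank)
    scale <- ifelse(probe_rank == 1L, 1,
                    stats::runif(length(probe_ids), 0.8, 1.2))
    vals <- lg[gene_of_probe, , drop = FALSE] * scale
    if (config$intensity_noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(length(vals), sd = config$intensity_noise_sd),
                            nrow(vals), ncol(vals))
    }
    rownames(vals) <- probe_ids
    pm <- data.frame(probe = probe_ids, gene = gene_of_probe,
                     stringsAsFactors = FALSE)
    expression_matrix(vals, platform = "intensity", probe_map = pm)
  })
}
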