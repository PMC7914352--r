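#' Validate a pipeline configuration
#'
#' A pipeline configuration is a nested list (usually read from YAML). It
#' either carries a `synth` block (overrides for [cohort_config()], always
#' including a `seed`) or an `inputs` block with file paths (`expr_counts`,
#' optionally `expr_intensity` + `probe_map`, `clinical`, `lr_db`, `gmt`).
#' Analysis blocks: `signatures` (`tcell`, `cd8`, `immune` names),
#' `clustering` (`k_counts`, `k_intensity`), `de` (thresholds, `test`),
#' `ora` (`min_overlap`, `fdr_max`), `gsea` (`n_perm`, `seed`), `ligrec`
#' (`tau`, `r_min`, `q_max`), `survival` (`endpoints`). Every source of
#' randomness must carry a seed at validation time, before any computation.
#'
#' @param config List or path to a YAML file.
#' @return The validated configuration (invisibly classed
#'   `PipelineConfig`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  synth_mode <- !is.null(config$synth)
  if (synth_mode) {
    if (is.null(config$synth$seed)) {
      stop("config error: `synth$seed` is required before any compute", call. = FALSE)
    }
  } else {
    need <- c("expr_counts", "clinical", "lr_db", "gmt")
    miss <- setdiff(need, names(config$inputs %||% list()))
    if (length(miss)) {
      stop("config error: missing input path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    for (p in unlist(config$inputs)) {
      if (!file.exists(p)) stop("config error: input file not found: ", p, call. = FALSE)
    }
    if (is.null(config$signatures$tcell)) {
      stop("config error: `signatures$tcell` names are required", call. = FALSE)
    }
  }
  if (!isFALSE(config$gsea$enabled %||% TRUE) && is.null(config$gsea$seed)) {
    stop("config error: `gsea$seed` is required before any compute", call. = FALSE)
  }
  structure(config, class = c("PipelineConfig", "list"))
}

#' Run the full immune-contexture analysis pipeline
#'
#' Orchestrates synthesize-or-load, signature scoring, immune subtyping, HLA
#' status, differential expression + enrichment (ORA and preranked GSEA),
#' ligand-receptor inference with the cross-platform funnel, and
#' survival/association statistics, writing every result as TSV into
#' `out_dir` together with a `run.log` recording every parameter and funnel
#' count. Re-running with the same configuration (and therefore the same
#' seeds) is bit-identical.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory results and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("tmecontext pipeline run", format_config(config))

  # --- stage: synthesize or load --------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (!is.null(config$synth)) {
    cohort <- stage("synthesize", {
      cfg <- do.call(cohort_config, config$synth)
      generate_cohort(cfg)
    })
    expr <- cohort$expr
    expr2 <- stage("synthesize", generate_microarray_view(expr, do.call(cohort_config, config$synth)))
    clinical <- cohort$clinical
    lrdb <- cohort$lr_db
    sigs <- cohort$signatures
    tcell <- config$signatures$tcell %||% synthetic_tcell_signatures()
    cd8 <- config$signatures$cd8 %||% tcell[1]
    immune <- config$signatures$immune %||% synthetic_immune_signatures()
    truth <- cohort$truth
  } else {
    inp <- config$inputs
    expr <- stage("load", read_expression(inp$expr_counts, "counts"))
    expr2 <- if (!is.null(inp$expr_intensity)) {
      stage("load", read_expression(inp$expr_intensity, "intensity", inp$probe_map))
    } else NULL
    clinical <- stage("load", read_clinical(inp$clinical))
    lrdb <- stage("load", read_lr_database(inp$lr_db))
    sigs <- stage("load", read_gmt(inp$gmt))
    tcell <- config$signatures$tcell
    cd8 <- config$signatures$cd8 %||% tcell[1]
    immune <- config$signatures$immune %||% names(sigs)
    truth <- NULL
  }

  # --- stage: signature scores ----------------------------------------
  scores <- stage("signature_scores", {
    z <- zscore_matrix(expr)
    score_signatures(z, sigs)
  })
  write_tsv(score_df(scores$scores, "signature"), file.path(out_dir, "signature_scores.tsv"))

  # --- stage: immune subtypes -----------------------------------------
  k_counts <- config$clustering$k_counts %||% 3L
  subtypes <- stage("subtyping",
                    assign_immune_subtypes(scores, tcell, cd8, k = k_counts,
                                           merge_smallest = (k_counts == 4L)))
  write_tsv(as.data.frame(subtypes), file.path(out_dir, "subtypes.tsv"))

  # --- stage: HLA status ----------------------------------------------
  hla <- NULL
  hla_c1 <- config$hla$class1 %||% truth$hla_class1_genes
  hla_c2 <- config$hla$class2 %||% truth$hla_class2_genes
  if (!is.null(hla_c1) && !is.null(hla_c2)) {
    hla <- stage("hla", hla_status(expr, hla_c1, hla_c2, k = 4L))
    write_tsv(as.data.frame(hla), file.path(out_dir, "hla.tsv"))
  }

  # --- stage: differential expression + enrichment --------------------
  rich_vs_rest <- stats::setNames(
    ifelse(subtypes$subtype == "immune_rich", "rich", "other"),
    subtypes$sample_id)
  de <- stage("differential_expression", {
    do.call(differential_expression,
            c(list(expr = expr, group_labels = rich_vs_rest),
              config$de %||% list()))
  })
  write_tsv(de, file.path(out_dir, "de_rich_vs_other.tsv"))

  ora <- stage("ora", {
    query <- de$gene[de$pass]
    if (length(query) >= 1L) {
      ora_hypergeometric(query, sigs, universe = de$gene,
                         min_overlap = config$ora$min_overlap %||% 3L,
                         fdr_max = config$ora$fdr_max %||% 0.05)
    } else NULL
  })
  if (!is.null(ora)) write_tsv(ora, file.path(out_dir, "enrichment_ora.tsv"))

  gsea <- NULL
  if (!isFALSE(config$gsea$enabled %||% TRUE)) {
    gsea <- stage("gsea", {
      ranking <- stats::setNames(sign(de$log2_fc) * -log10(pmax(de$p_value, 1e-300)),
                                 de$gene)
      gsea_preranked(ranking, sigs,
                     n_perm = config$gsea$n_perm %||% 1000L,
                     seed = config$gsea$seed)
    })
    write_tsv(gsea, file.path(out_dir, "enrichment_gsea.tsv"))
  }

  # --- stage: ligand-receptor inference -------------------------------
  tau <- config$ligrec$tau %||% 0.5
  lig <- stage("ligrec", {
    rho_a <- pair_correlation(expr, lrdb)
    conf_a <- select_confident(rho_a, tau)
    if (!is.null(expr2)) {
      rho_b <- pair_correlation(expr2, lrdb)
      conf_b <- select_confident(rho_b, tau)
    } else {
      rho_b <- NULL; conf_b <- conf_a
    }
    cons <- consensus_and_filter(conf_a, conf_b,
                                 background_pairs = lrdb[lrdb$background, ])
    infil <- infiltration_score(scores, intersect(immune, rownames(scores$scores)))
    screen <- if (nrow(cons$retained)) {
      sm <- lr_score_matrix(expr, cons$retained)
      infiltration_screen(sm, infil,
                          r_min = config$ligrec$r_min %||% 0.5,
                          q_max = config$ligrec$q_max %||% 0.05)
    } else NULL
    list(rho_a = rho_a, rho_b = rho_b, consensus = cons, screen = screen,
         infiltration = infil)
  })
  report <- merge(lig$rho_a[, c("ligand", "receptor", "rho", "background")],
                  data.frame(ligand = lig$consensus$retained$ligand,
                             receptor = lig$consensus$retained$receptor,
                             retained = TRUE, stringsAsFactors = FALSE),
                  by = c("ligand", "receptor"), all.x = TRUE)
  report$retained[is.na(report$retained)] <- FALSE
  if (!is.null(lig$screen)) {
    key <- paste(report$ligand, report$receptor, sep = ":")
    idx <- match(key, lig$screen$pair)
    report$infiltration_rho <- lig$screen$rho[idx]
    report$infiltration_fdr <- lig$screen$fdr[idx]
    report$infiltration_flagged <- lig$screen$flagged[idx]
  }
  write_tsv(report, file.path(out_dir, "lr_report.tsv"))
  log_lines <- c(log_lines, "", "L-R funnel:",
                 paste(names(lig$consensus$funnel), lig$consensus$funnel,
                       sep = " = "))

  # --- stage: survival and association --------------------------------
  endpoints <- config$survival$endpoints %||% c("os", "rfs")
  surv_rows <- lapply(endpoints, function(ep) {
    t_col <- paste0(ep, "_time"); e_col <- paste0(ep, "_event")
    grp <- rich_vs_rest[clinical$sample_id]
    lr <- stage("survival", logrank_test(clinical[[t_col]], clinical[[e_col]], grp))
    data.frame(endpoint = ep, comparison = "immune_rich_vs_other",
               statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
               stringsAsFactors = FALSE)
  })
  surv_df <- do.call(rbind, surv_rows)
  write_tsv(surv_df, file.path(out_dir, "survival_logrank.tsv"))
  assoc <- stage("association",
                 association_table(clinical, rich_vs_rest))
  write_tsv(assoc, file.path(out_dir, "association_table.tsv"))

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(expr = expr, expr_intensity = expr2, clinical = clinical,
                 signatures = sigs, scores = scores, subtypes = subtypes,
                 hla = hla, de = de, ora = ora, gsea = gsea, ligrec = lig,
                 survival = surv_df, association = assoc, truth = truth,
                 out_dir = out_dir))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

score_df <- function(m, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

# Flat "key = value" rendering of the nested config for run.log, so every
# number in the report traces back to a logged parameter.
format_config <- function(config, prefix = "") {
  unlist(lapply(names(config), function(nm) {
    val <- config[[nm]]
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(val)) format_config(val, key)
    else paste0(key, " = ", paste(format(val), collapse = ","))
  }))
}
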