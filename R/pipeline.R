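## Full dual-marker workflow from one configuration: lineage assignment ->
## haplotypes -> per-lineage mismatch/expansion/dating -> diversity ->
## admixture grid -> Evanno -> run alignment -> delta-Qbar permutation test.

# internal: deterministic per-stage seed derived from the master seed and
# the stage name, stable under pipeline edits; always < 2^31
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

# internal: fill missing config entries with defaults (paper-scale)
pipeline_defaults <- function(cfg) {
  def <- list(
    window = NULL,                       # 0-based half-open [start, end)
    mismatch = list(n_iter = 10000L),
    calibration = NULL,                  # list(distance, divergence_years,
                                         #      fragment_length, generation_years)
    admixture = list(k_range = 1:8, n_runs = 20L, n_iterations = 110000L,
                     burn_in_fraction = 0.10, freq_model = "correlated"),
    permutation = list(n_perm = 100000L, sidedness = "greater",
                       cluster_column = "auto"),
    seed = 0L
  )
  for (nm in names(def)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- def[[nm]]
    } else if (is.list(def[[nm]])) {
      for (sub in names(def[[nm]])) {
        if (is.null(cfg[[nm]][[sub]])) cfg[[nm]][[sub]] <- def[[nm]][[sub]]
      }
    }
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full dual-marker pipeline
#'
#' Executes every stage whose inputs are present in the configuration
#' (mtDNA-only and nuclear-only runs are supported), writing flat TSV/JSON
#' outputs plus a manifest into `out_dir`. Stage-level seeds are derived
#' deterministically from the master seed, so identical configuration and
#' seed reproduce identical outputs.
#'
#' @param config A configuration list, or path to a JSON file holding one.
#'   Recognised entries: `sequences`, `references`, `genotypes`,
#'   `genotype_dialect`, `metadata` (paths); `window` (0-based half-open
#'   `[start, end)` analysis window); `mismatch$n_iter`; `calibration`
#'   (distance, divergence_years, fragment_length, generation_years);
#'   `admixture` (k_range, n_runs, n_iterations, burn_in_fraction,
#'   freq_model); `permutation` (n_perm, sidedness, cluster_column); `seed`.
#' @param out_dir Results directory (created; one subdirectory per stage).
#' @return The manifest list, invisibly. A stage failure is recorded in the
#'   manifest (written before the error is re-signalled).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- pipeline_defaults(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "lineagemix",
                   version = as.character(utils::packageVersion("lineagemix")),
                   seed = cfg$seed, stages = list())
  failed <- NULL

  run_stage <- function(name, fun) {
    if (!is.null(failed)) return(invisible(NULL))
    dir.create(file.path(out_dir, name), showWarnings = FALSE)
    res <- tryCatch(fun(file.path(out_dir, name), stage_seed(cfg$seed, name)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      failed <<- res
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  have_seq <- !is.null(cfg$sequences)
  have_gt <- !is.null(cfg$genotypes)

  records <- NULL
  lineage_tab <- NULL
  meta <- if (!is.null(cfg$metadata)) read_metadata(cfg$metadata) else NULL

  if (have_seq) {
    records <- read_fasta(cfg$sequences)
    if (!is.null(cfg$window)) {
      records <- substring(records, cfg$window[1L] + 1L, cfg$window[2L])
    }

    run_stage("lineages", function(dir, seed) {
      refs_raw <- read_fasta(cfg$references)
      if (!is.null(cfg$window)) {
        refs_raw <- substring(refs_raw, cfg$window[1L] + 1L, cfg$window[2L])
      }
      refs <- lineage_references(names(refs_raw), unname(refs_raw))
      lineage_tab <<- assign_lineages(records, refs)
      list(files = write_tsv(lineage_tab, file.path(dir, "lineage_assignment.tsv")))
    })

    run_stage("haplotypes", function(dir, seed) {
      haps <- collapse_haplotypes(records)
      tab <- data.frame(haplotype = names(haps$haplotypes),
                        count = haps$counts,
                        members = vapply(haps$members, paste, character(1),
                                         collapse = ","),
                        sequence = unname(haps$haplotypes))
      net <- if (length(haps$haplotypes) >= 2L) median_joining_network(haps) else NULL
      files <- write_tsv(tab, file.path(dir, "haplotypes.tsv"))
      if (!is.null(net)) {
        files <- c(files, write_network(net, file.path(dir, "network_edges.tsv")))
      }
      list(files = files, n_haplotypes = length(haps$haplotypes))
    })

    run_stage("mismatch", function(dir, seed) {
      groups <- if (!is.null(lineage_tab)) {
        g <- split(lineage_tab$sample_id, lineage_tab$lineage)
        g[!names(g) %in% c("unassigned", "ambiguous")]
      } else {
        list(all = names(records))
      }
      files <- character(0)
      fits <- list()
      for (g in names(groups)) {
        if (length(groups[[g]]) < 3L) next
        recs <- records[groups[[g]]]
        mm <- mismatch_distribution(recs)
        files <- c(files, write_tsv(
          data.frame(differences = names(mm$counts), pairs = mm$counts),
          file.path(dir, paste0("mismatch_", g, ".tsv"))))
        fit <- fit_expansion(mm)
        fit <- bootstrap_expansion_test(recs, fit,
                                        n_iter = cfg$mismatch$n_iter,
                                        seed = seed + match(g, names(groups)))
        out <- list(lineage = g, tau = fit$tau, theta0 = fit$theta0,
                    theta1 = fit$theta1, ssd = fit$ssd_obs,
                    p_value = fit$p_value, tau_ci = fit$tau_ci)
        if (!is.null(cfg$calibration)) {
          cal <- do.call(dating_calibration, cfg$calibration)
          out$dating <- date_expansion(fit$tau, cal, fit$tau_ci)
        }
        fits[[g]] <- out
      }
      fp <- file.path(dir, "expansion_fits.json")
      jsonlite::write_json(fits, fp, auto_unbox = TRUE, digits = NA)
      list(files = c(files, fp))
    })
  }

  gt <- NULL
  if (have_gt) {
    dialect <- if (is.null(cfg$genotype_dialect)) "csv" else cfg$genotype_dialect
    gt <- read_genotypes(cfg$genotypes, dialect = dialect)

    run_stage("diversity", function(dir, seed) {
      dt <- diversity_table(gt)
      nn <- null_allele_check(gt)
      hwe <- do.call(rbind, lapply(gt$locus_names, function(l) {
        r <- hwe_exact_test(gt, l, n_mc = 2000L, seed = seed)
        data.frame(locus = l, p_value = r$p_value, n_typed = r$n_typed)
      }))
      list(files = c(write_tsv(dt, file.path(dir, "diversity.tsv")),
                     write_tsv(nn, file.path(dir, "null_alleles.tsv")),
                     write_tsv(hwe, file.path(dir, "hwe.tsv"))))
    })

    run_stage("admixture", function(dir, seed) {
      ad <- cfg$admixture
      runs <- list()
      for (k in ad$k_range) {
        for (r in seq_len(ad$n_runs)) {
          cfg_k <- admixture_config(k, freq_model = ad$freq_model,
                                    n_iterations = ad$n_iterations,
                                    burn_in_fraction = ad$burn_in_fraction,
                                    seed = seed + 1000L * k + r)
          runs[[length(runs) + 1L]] <- run_admixture_mcmc(gt, cfg_k)
        }
      }
      ev <- evanno_delta_k(runs)
      files <- write_tsv(as.data.frame(ev), file.path(dir, "evanno.tsv"))
      sel <- attr(ev, "selected_k")
      aligned <- NULL
      ks_to_align <- unique(stats::na.omit(c(sel, if (3L %in% ad$k_range) 3L)))
      for (k in ks_to_align) {
        if (k < 2L) next
        al <- align_runs(Filter(function(x) x$k_clusters == k, runs))
        qdf <- data.frame(sample_id = rownames(al$consensus_q),
                          round(al$consensus_q, 6))
        names(qdf)[-1L] <- paste0("Q", seq_len(k))
        files <- c(files, write_tsv(qdf, file.path(dir,
                   sprintf("consensus_q_K%d.tsv", k))))
        if (is.null(aligned) || k == 3L) aligned <- al
      }
      assign("pipeline_aligned_q", aligned, envir = pipeline_state)
      list(files = files, selected_k = sel)
    })

    run_stage("permtest", function(dir, seed) {
      aligned <- get0("pipeline_aligned_q", envir = pipeline_state)
      if (is.null(aligned)) stop("no aligned admixture runs available")
      qm <- aligned$consensus_q
      lin <- NULL
      if (!is.null(meta) && any(!is.na(meta$mito_lineage))) {
        lin <- meta$mito_lineage[match(rownames(qm), meta$sample_id)]
      } else if (!is.null(lineage_tab)) {
        lin <- lineage_tab$lineage[match(rownames(qm), lineage_tab$sample_id)]
      }
      if (is.null(lin)) stop("no mitochondrial lineage labels available")
      keep <- !is.na(lin) & !lin %in% c("unassigned", "ambiguous")
      qm <- qm[keep, , drop = FALSE]
      lin <- factor(lin[keep])
      if (nlevels(lin) != 2L) stop("permutation test needs exactly two lineages")
      pc <- cfg$permutation
      col <- pc$cluster_column
      if (identical(col, "auto")) {
        deltas <- apply(qm, 2L, delta_q_statistic, labels = lin)
        col <- which.max(abs(deltas))
        note <- "column chosen as argmax |delta-Qbar| (exploratory)"
      } else {
        note <- NULL
      }
      res <- permutation_test_delta_q(qm[, col], lin, n_perm = pc$n_perm,
                                      seed = seed, sidedness = pc$sidedness)
      fp <- file.path(dir, "delta_q_test.json")
      jsonlite::write_json(list(cluster_column = col, note = note,
                                group_levels = levels(lin),
                                group_sizes = res$group_sizes,
                                mean_q_per_group = res$mean_q_per_group,
                                delta_q = res$delta_q, p_value = res$p_value,
                                n_permutations = res$n_permutations),
                           fp, auto_unbox = TRUE, digits = NA)
      list(files = fp)
    })
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(failed)) {
    stop("pipeline stage failed (see manifest): ", conditionMessage(failed))
  }
  invisible(manifest)
}

# internal mutable slot for cross-stage hand-off within one pipeline call
pipeline_state <- new.env(parent = emptyenv())
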