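# Configuration-driven orchestration of the full desk-scale flow:
# simulate -> adjust -> per-study GWAS -> meta -> heterogeneity filter ->
# conditional selection -> clumping -> variance explained -> MR.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Defaults give a small but
#' complete three-study run: shared variant panel with LD blocks, planted
#' causal effects spanning common-small to rare-large, instrument artifacts
#' on every study, and an MR stage over the discovered sentinels.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param n_per_study named sample sizes for studies A, B, C.
#' @param n_variants shared variant panel size.
#' @param ld_block_size LD block size.
#' @param maf_spectrum MAF spectrum passed to [simulate_genotypes()].
#' @param indices measured indices to simulate and analyse.
#' @param architecture an [architecture_spec()]; the default plants seven
#'   causal variants (common effects 0.3-0.45 SD, one rare 1 SD effect)
#'   across RBC, MCV, HGB, PLT and MPV with polygenic background 0.2.
#' @param artifacts a [technical_artifacts()] spec applied to each study.
#' @param alpha genome-wide significance level (8.31e-9).
#' @param het_threshold heterogeneity score filter (5.2).
#' @param clump_r2 LD clumping threshold (0.8).
#' @param block_gap conditional-analysis block gap in bp (1e7).
#' @param mr_alpha family-wise MR level (0.05).
#' @param mr_theta named true causal effects used to simulate the disease
#'   outcome for the MR stage.
#' @param knots,env_knots spline basis dimensions for the adjustment stages
#'   (reduced from the full-scale 50/30/30 defaults for desk runtime).
#' @param out_dir output directory for stage artifacts and the manifest.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_study = c(A = 800, B = 800, C = 800),
                            n_variants = 300,
                            ld_block_size = 10,
                            maf_spectrum = list(type = "uniform",
                                                min = 0.02, max = 0.5),
                            indices = c("RBC", "MCV", "HGB", "PLT", "MPV"),
                            architecture = NULL,
                            artifacts = technical_artifacts(
                              drift_slope = c(M1 = 0.08, M2 = -0.04, M3 = 0.02),
                              calibration_jumps = tibble(
                                instrument = "M2", day = 365L, size = 0.05)),
                            alpha = 8.31e-9, het_threshold = 5.2,
                            clump_r2 = 0.8, block_gap = 1e7,
                            mr_alpha = 0.05,
                            mr_theta = c(PLT = 0.3, MCV = -0.2),
                            knots = list(drift = 12, bivariate = 10,
                                         seasonal = 8),
                            env_knots = list(age = 10, body = 10,
                                             packyears = 6, alcohol = 6,
                                             period = 6),
                            out_dir = tempfile("hemegwas_run_")) {
  if (is.null(architecture)) {
    architecture <- architecture_spec(
      effects = tribble(
        ~variant_id, ~index, ~beta,
        "var0010", "RBC", 0.35,
        "var0050", "MCV", 0.45,
        "var0051", "MCV", -0.30,
        "var0120", "HGB", 0.35,
        "var0170", "PLT", 0.40,
        "var0171", "PLT", 0.30,
        "var0230", "MPV", 0.45),
      h2_poly = c(RBC = 0.2, MCV = 0.2, HGB = 0.2, PLT = 0.2, MPV = 0.2))
  }
  cfg <- list(seed = seed, n_per_study = n_per_study,
              n_variants = n_variants, ld_block_size = ld_block_size,
              maf_spectrum = maf_spectrum, indices = indices,
              architecture = architecture, artifacts = artifacts,
              alpha = alpha, het_threshold = het_threshold,
              clump_r2 = clump_r2, block_gap = block_gap,
              mr_alpha = mr_alpha, mr_theta = mr_theta,
              knots = knots, env_knots = env_knots, out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a configuration list to validate.
#' @export
validate_pipeline_config <- function(config) {
  required <- c("seed", "n_per_study", "n_variants", "ld_block_size",
                "maf_spectrum", "indices", "architecture", "artifacts",
                "alpha", "het_threshold", "clump_r2", "block_gap",
                "mr_alpha", "mr_theta", "knots", "env_knots", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(paste0("Pipeline config is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  thresholds <- c(alpha = config$alpha, het = config$het_threshold,
                  clump_r2 = config$clump_r2, gap = config$block_gap,
                  mr_alpha = config$mr_alpha)
  if (any(thresholds <= 0)) abort("All thresholds must be positive.")
  if (!all(c("A", "B", "C") %in% names(config$n_per_study))) {
    abort("`n_per_study` must name studies A, B and C.")
  }
  invisible(config)
}

.write_stage <- function(tab, stage, file, out_dir, manifest, seed) {
  path <- file.path(out_dir, file)
  readr::write_tsv(tab, path)
  bind_rows(manifest, tibble(stage = stage, file = file,
                             checksum = unname(tools::md5sum(path)),
                             seed = seed))
}

#' Run the full desk-scale pipeline
#'
#' Executes simulate -> adjust -> GWAS x3 -> meta -> heterogeneity filter ->
#' conditional selection -> clump -> variance explained -> MR, writing every
#' stage's outputs as TSV under `config$out_dir` together with a manifest
#' (file, stage, md5 checksum, seed). Reruns with an identical configuration
#' are bit-identical. A stage failure halts with the stage name; the partial
#' manifest is saved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the `manifest` tibble and in-memory stage
#'   results (`meta` per index, `conditional` per index, `clumps`,
#'   `variance_explained`, `mr`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble(stage = character(), file = character(),
                     checksum = character(), seed = integer())
  save_manifest <- function() {
    readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  }
  stage <- "simulate"
  result <- tryCatch({
    studies <- c("A", "B", "C")
    analyzers <- c(A = "coulter", B = "sysmex", C = "coulter")
    cohorts <- list(); genos <- list(); phenos <- list()
    for (i in seq_along(studies)) {
      st <- studies[i]
      sd_g <- derive_seed(config$seed, i)
      g <- simulate_genotypes(config$n_per_study[[st]], config$n_variants,
                              maf_spectrum = config$maf_spectrum,
                              ld_block_size = config$ld_block_size,
                              seed = sd_g)
      g$sample_ids <- rownames(g$dosage) <- paste0(st, g$sample_ids)
      ch <- simulate_cohort(g, architecture = config$architecture,
                            artifacts = config$artifacts,
                            study_id = st, analyzer = analyzers[[st]],
                            indices = config$indices,
                            seed = derive_seed(config$seed, 10 + i))
      genos[[st]] <- g; cohorts[[st]] <- ch
      samples_out <- ch$samples |>
        mutate(acq_time = format(.data$acq_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
               ven_time = format(.data$ven_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"))
      manifest <- .write_stage(samples_out, "simulate",
                               sprintf("cohort_%s.tsv", st),
                               config$out_dir, manifest, sd_g)
    }

    stage <- "adjust"
    for (st in studies) {
      adj <- adjust_cohort(cohorts[[st]], knots = config$knots,
                           env_knots = config$env_knots)
      phenos[[st]] <- adj$phenotypes
      manifest <- .write_stage(adj$phenotypes, "adjust",
                               sprintf("phenotypes_%s.tsv", st),
                               config$out_dir, manifest, config$seed)
    }

    stage <- "gwas"
    idx_all <- intersect(names(phenos[["A"]]),
                         blood_index_registry()$index)
    sumstats <- list()
    for (idx in idx_all) {
      per_study <- list()
      for (st in studies) {
        covs <- data.frame(center = cohorts[[st]]$samples$center)
        per_study[[st]] <- run_gwas(genos[[st]], phenos[[st]][[idx]], covs)
      }
      sumstats[[idx]] <- per_study
    }
    manifest <- .write_stage(
      purrr::imap_dfr(sumstats, function(ps, idx) {
        purrr::imap_dfr(ps, function(st_tab, st) {
          mutate(st_tab, index = idx, study = st)
        })
      }),
      "gwas", "sumstats_per_study.tsv", config$out_dir, manifest,
      config$seed)

    stage <- "meta"
    metas <- purrr::imap(sumstats, function(ps, idx) {
      het_filter(ivw_meta(ps, alpha = config$alpha),
                 threshold = config$het_threshold)
    })
    manifest <- .write_stage(
      purrr::imap_dfr(metas, ~mutate(as_tibble(.x), index = .y)),
      "meta", "meta_sumstats.tsv", config$out_dir, manifest, config$seed)

    stage <- "condsel"
    pooled_dosage <- do.call(rbind, purrr::map(genos, "dosage"))
    pooled_geno <- structure(
      list(dosage = pooled_dosage, variants = genos[["A"]]$variants,
           sample_ids = rownames(pooled_dosage)),
      class = "genotype_matrix")
    conditional <- list()
    for (idx in names(metas)) {
      m <- metas[[idx]]
      sig <- m |> filter(.data$significant, .data$het_pass)
      if (!nrow(sig)) next
      y <- unlist(purrr::map(phenos, idx), use.names = FALSE)
      covs <- data.frame(
        study = rep(studies, vapply(phenos, nrow, 1L)),
        center = unlist(purrr::map(cohorts, ~.x$samples$center),
                        use.names = FALSE))
      blocks <- partition_blocks(sig$pos, sig$chrom, gap = config$block_gap)
      sel_ids <- character(0)
      for (b in unique(blocks$block)) {
        cand <- sig$variant_id[sig$pos %in% blocks$pos[blocks$block == b]]
        cm <- stepwise_select(pooled_geno, y, covs, candidates = cand,
                              alpha = config$alpha)
        sel_ids <- c(sel_ids, cm$variant_id)
      }
      if (!length(sel_ids)) next
      final <- stepwise_select(pooled_geno, y, covs, candidates = sel_ids,
                               alpha = config$alpha, start = "saturated")
      conditional[[idx]] <- final
    }
    if (length(conditional)) {
      manifest <- .write_stage(
        purrr::imap_dfr(conditional, ~mutate(tidy(.x), index = .y)),
        "condsel", "conditional_models.tsv", config$out_dir, manifest,
        config$seed)
    }

    stage <- "clump"
    clumps <- NULL
    if (length(conditional)) {
      assoc <- purrr::imap_dfr(conditional, function(cm, idx) {
        m <- metas[[idx]]
        tibble(variant_id = cm$variant_id, trait = idx,
               p = m$p[match(cm$variant_id, m$variant_id)])
      })
      r2 <- dosage_r2(pooled_geno, unique(assoc$variant_id))
      clumps <- clump(assoc, r2, threshold = config$clump_r2)
      manifest <- .write_stage(clumps, "clump", "clumps.tsv",
                               config$out_dir, manifest, config$seed)
    }

    stage <- "varexp"
    varexp <- NULL
    if (length(conditional)) {
      varexp <- purrr::imap_dfr(conditional, function(cm, idx) {
        y <- unlist(purrr::map(phenos, idx), use.names = FALSE)
        common <- cm$variant_id[
          pooled_geno$variants$maf[match(cm$variant_id,
                                         pooled_geno$variants$variant_id)] >= 0.05]
        grp <- list(common = common,
                    lowfreq_rare = setdiff(cm$variant_id, common))
        ve <- variance_explained_by_group(pooled_geno, y, grp)
        mutate(ve$by_group, index = idx, total_r2 = ve$total_r2)
      })
      manifest <- .write_stage(varexp, "varexp", "variance_explained.tsv",
                               config$out_dir, manifest, config$seed)
    }

    stage <- "mr"
    mr_out <- NULL
    if (!is.null(clumps)) {
      sentinels <- clumps |> filter(.data$sentinel) |> pull("variant_id")
      k_idx <- intersect(config$indices, names(metas))
      if (length(sentinels) >= 3) {
        bx <- vapply(k_idx, function(idx) {
          m <- metas[[idx]]
          m$beta[match(sentinels, m$variant_id)]
        }, numeric(length(sentinels)))
        # keep only indices the instruments actually move, to preserve rank,
        # and cap the exposure count below the instrument count
        keep_idx <- colSums(abs(bx) > 0.05, na.rm = TRUE) > 0
        bx <- bx[, keep_idx, drop = FALSE]
        if (ncol(bx) > length(sentinels) - 2) {
          strength <- colSums(bx^2, na.rm = TRUE)
          keep2 <- rank(-strength, ties.method = "first") <=
            length(sentinels) - 2
          bx <- bx[, keep2, drop = FALSE]
        }
        if (ncol(bx) >= 1 && length(sentinels) > ncol(bx)) {
          sex <- vapply(colnames(bx), function(idx) {
            m <- metas[[idx]]
            m$se[match(sentinels, m$variant_id)]
          }, numeric(length(sentinels)))
          theta <- setNames(rep(0, ncol(bx)), colnames(bx))
          th_in <- config$mr_theta[intersect(names(config$mr_theta),
                                             colnames(bx))]
          theta[names(th_in)] <- th_in
          vmeta <- pooled_geno$variants[
            match(sentinels, pooled_geno$variants$variant_id), ]
          withr::with_seed(derive_seed(config$seed, 99), {
            sey <- rep(0.05, length(sentinels))
            by <- drop(bx %*% theta) + rnorm(length(sentinels), 0, sey)
          })
          mrd <- structure(list(
            variants = tibble(variant_id = sentinels, chrom = vmeta$chrom,
                              pos = vmeta$pos, mhc = FALSE,
                              known_disease = FALSE, n_index_classes = 1L),
            Bx = bx, SEx = sex, by = by, sey = sey,
            index_names = colnames(bx),
            truth = list(theta = theta)), class = "mr_dataset")
          bon <- bonferroni_threshold(config$mr_alpha, ncol(bx), 1)
          est <- tryCatch(mvmr_ivw(mrd), error = function(e) NULL)
          if (!is.null(est)) {
            egger <- tryCatch(mvmr_egger_intercepts(mrd),
                              error = function(e) NULL)
            mr_out <- list(dataset = mrd, result = est,
                           threshold = bon$threshold, egger = egger)
            manifest <- .write_stage(
              tidy(est) |> mutate(pass = .data$p < bon$threshold),
              "mr", "mr_results.tsv", config$out_dir, manifest, config$seed)
          } else {
            warn("MR stage skipped: sentinel exposure matrix is rank deficient.")
          }
        }
      }
    }
    save_manifest()
    list(manifest = manifest, cohorts = cohorts, phenotypes = phenos,
         meta = metas, conditional = conditional, clumps = clumps,
         variance_explained = varexp, mr = mr_out)
  }, error = function(e) {
    save_manifest()
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
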