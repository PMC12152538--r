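#' Pipeline configuration
#'
#' Bundles every stage's configuration and the stage toggles. One global
#' seed deterministically derives per-stage seeds (see [stage_seed()]), so
#' stages draw from independent streams.
#'
#' @param generator [generator_config()] for the simulate stage.
#' @param thresholds [at_thresholds()].
#' @param proportion SCN proportional threshold.
#' @param cvconfig [cv_config()] for the classifier stage.
#' @param n_parcels,n_networks,n_perm Spin-test parcellation and
#'   permutation settings.
#' @param n_validation_cohorts Additional synthetic cohorts generated for
#'   the meta-analysis stage.
#' @param stages Character vector of enabled stages, in dependency order.
#' @param seed Global seed.
#' @return List of class `morphocov_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            thresholds = at_thresholds(),
                            proportion = 0.35,
                            cvconfig = cv_config(),
                            n_parcels = 100, n_networks = 7, n_perm = 500,
                            n_validation_cohorts = 3,
                            stages = c("simulate", "prep", "scn", "sgcc",
                                       "assoc", "meta", "spin"),
                            seed = 1L) {
  structure(list(generator = generator, thresholds = thresholds,
                 proportion = proportion, cvconfig = cvconfig,
                 n_parcels = n_parcels, n_networks = n_networks,
                 n_perm = n_perm,
                 n_validation_cohorts = n_validation_cohorts,
                 stages = stages, seed = as.integer(seed)),
            class = "morphocov_pipeline_config")
}

#' Deterministic per-stage seed
#'
#' Mixes the global seed with a hash of the stage name so stages use
#' decoupled random streams. Always in `[1, 2^31 - 2]`.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 94906265) * 22 + (h * 2654435) %% 2147483646) %%
    2147483646L + 1L
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Serialise a network as an edge list
#'
#' @param net A `morphocov_network`.
#' @return Tibble: `region_a`, `region_b`, `z_weight` (retained edges only).
#' @export
network_to_edges <- function(net) {
  W <- net$W
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  tibble::tibble(region_a = net$regions[idx[, 1]],
                 region_b = net$regions[idx[, 2]],
                 z_weight = W[idx])
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every stage
#' output under `out_dir`, and returns (and writes) a manifest holding the
#' configuration snapshot, per-stage logs and an MD5 hash of every output
#' file. A stage whose dependency is disabled refuses to run with a clear
#' message; a stage failure is recorded in the manifest before the error is
#' re-raised, leaving completed outputs intact.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "morphocov_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  deps <- list(prep = "simulate", scn = "prep", sgcc = "prep",
               assoc = "prep", meta = "assoc", spin = "meta")
  manifest <- list(config = .config_snapshot(config), stages = list())
  env <- new.env()
  for (st in stages) {
    need <- deps[[st]]
    if (!is.null(need) && !(need %in% stages)) {
      stop("stage '", st, "' requires stage '", need,
           "' which is not enabled")
    }
    res <- tryCatch(
      .run_stage(st, config, env, out_dir),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- list(status = "failed",
                                    error = conditionMessage(res))
      .write_manifest(manifest, out_dir)
      stop("stage '", st, "' failed: ", conditionMessage(res))
    }
    res$status <- "ok"
    res$hashes <- as.list(unname(tools::md5sum(unlist(res$outputs))))
    names(res$hashes) <- basename(unlist(res$outputs))
    manifest$stages[[st]] <- res
  }
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

.config_snapshot <- function(config) {
  rapply(unclass(config), f = function(x) x, how = "replace")
}

.run_stage <- function(st, config, env, out_dir) {
  switch(st,
    simulate = {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, "simulate")
      env$cohort <- generate_cohort(gen)
      env$parcellation <- generate_sphere_parcellation(
        config$n_parcels, config$n_networks,
        seed = stage_seed(config$seed, "parcellation"))
      f1 <- file.path(out_dir, "cohort.csv")
      utils::write.csv(env$cohort, f1, row.names = FALSE)
      f2 <- .write_tsv(env$parcellation,
                       file.path(out_dir, "parcellation.tsv"))
      list(outputs = list(f1, f2),
           log = list(n_sessions = nrow(env$cohort)))
    },
    prep = {
      env$prepped <- prepare_cohort(env$cohort, config$thresholds)
      f1 <- file.path(out_dir, "cohort_prepped.csv")
      utils::write.csv(env$prepped, f1, row.names = FALSE)
      f2 <- .write_tsv(summarize_demographics(env$prepped),
                       file.path(out_dir, "demographics.tsv"))
      list(outputs = list(f1, f2),
           log = c(attr(env$prepped, "drop_log"),
                   list(n_subjects = nrow(env$prepped))))
    },
    scn = {
      groups <- unique(env$prepped$at_group)
      env$metrics <- list()
      files <- list()
      for (g in groups) {
        sub <- env$prepped[env$prepped$at_group == g, , drop = FALSE]
        net <- build_scn(volume_matrix(sub),
                         .covariate_matrix(sub, c("age", "sex")),
                         proportion = config$proportion)
        gm <- graph_metrics(net, mode = "binary")
        env$metrics[[g]] <- gm
        f <- .write_tsv(network_to_edges(net),
                        file.path(out_dir, paste0("scn_", g, ".tsv")))
        files <- c(files, f)
      }
      tab <- dplyr::bind_rows(lapply(names(env$metrics), function(g) {
        gm <- env$metrics[[g]]
        tibble::tibble(group = g,
                       global_efficiency = gm$global_efficiency,
                       path_length = gm$path_length,
                       global_clustering = gm$global_clustering,
                       small_worldness = gm$small_worldness,
                       mean_degree = mean(gm$degree))
      }))
      f <- .write_tsv(tab, file.path(out_dir, "scn_metrics.tsv"))
      cmp <- compare_groups(lapply(env$metrics, function(gm) {
        list(degree = gm$degree, clustering = gm$clustering,
             efficiency = gm$efficiency)
      }))
      f2 <- .write_tsv(cmp, file.path(out_dir, "scn_comparisons.tsv"))
      list(outputs = c(files, list(f, f2)),
           log = list(groups = names(env$metrics)))
    },
    sgcc = {
      vols <- volume_matrix(env$prepped)
      res <- sgcc_by_stratum(vols, env$prepped$at_group, method = "pca2d",
                             seed = stage_seed(config$seed, "sgcc"))
      f <- .write_tsv(res, file.path(out_dir, "sgcc.tsv"))
      list(outputs = list(f), log = list(sgcc = res$sgcc))
    },
    assoc = {
      env$assoc <- list(
        amyloid = per_region_association(
          env$prepped, c("A_T_MINUS", "CONTROL")),
        tau_given_amyloid = per_region_association(
          env$prepped, c("A_T_PLUS", "A_T_MINUS"))
      )
      files <- lapply(names(env$assoc), function(nm) {
        .write_tsv(env$assoc[[nm]],
                   file.path(out_dir, paste0("assoc_", nm, ".tsv")))
      })
      list(outputs = files,
           log = list(n_selected = vapply(env$assoc, function(a)
             sum(a$selected), integer(1))))
    },
    meta = {
      gens <- lapply(seq_len(config$n_validation_cohorts), function(i) {
        g <- config$generator
        g$seed <- stage_seed(config$seed, paste0("validation", i))
        g
      })
      env$meta <- list()
      files <- list()
      for (nm in names(env$assoc)) {
        contrast <- if (nm == "amyloid") c("A_T_MINUS", "CONTROL") else
          c("A_T_PLUS", "A_T_MINUS")
        studies <- c(list(discovery = env$assoc[[nm]]),
                     lapply(gens, function(g) {
                       per_region_association(
                         prepare_cohort(generate_cohort(g),
                                        config$thresholds), contrast)
                     }))
        env$meta[[nm]] <- pool_regions(studies)
        files <- c(files, .write_tsv(
          env$meta[[nm]], file.path(out_dir, paste0("meta_", nm, ".tsv"))))
      }
      list(outputs = files,
           log = list(n_pooled = vapply(env$meta, nrow, integer(1))))
    },
    spin = {
      files <- list()
      for (nm in names(env$meta)) {
        mt <- env$meta[[nm]]
        sig <- mt$region[mt$p_fdr < 0.05]
        if (length(sig) == 0) next
        owner <- assign_parcels_to_regions(
          env$parcellation, config$generator$region_names,
          seed = stage_seed(config$seed, "parcel_regions"))
        res <- spin_null(owner %in% sig, env$parcellation,
                         n_perm = config$n_perm,
                         seed = stage_seed(config$seed,
                                           paste0("spin_", nm)))
        files <- c(files, .write_tsv(
          res, file.path(out_dir, paste0("spin_", nm, ".tsv"))))
      }
      list(outputs = files, log = list(n_maps = length(files)))
    },
    stop("unknown stage: ", st)
  )
}
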