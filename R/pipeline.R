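# End-to-end pipeline runner: simulate (or read) -> epochs -> entropy
# profiles -> features -> gf factor -> group PLSR, with a resolved-config
# snapshot, per-stage logging and output checksums for reproducibility.

default_config <- function() {
  list(out_dir = "neurocx-run", seed = 1L,
       simulate = NULL, input = NULL,
       epoch = list(length = 10240, amp_threshold = 111),
       mmse = list(M = 2, tau = 1, r = 0.15, eps_max = 12,
                   variant = "per_channel"),
       sets = channel_set_names(),
       groups = "all",
       plsr = list(ncomp = "auto", selector = "local_min",
                   max_components = 10, n_boot = 1000, n_perm = 1000,
                   alpha = 0.05, folds = "loo"))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("[.]ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stopf("config must be a list or a path to one")
  merge_config(default_config(), config)
}

#' Validate a pipeline configuration
#'
#' Report-only checks: errors for unknown channel sets, unusable epoch
#' geometry or missing inputs; a warning when the coarsest-scale series
#' falls below the `p * 10^m` sample-count guideline for stable entropy
#' estimates.
#'
#' @param config Configuration list (or YAML/JSON path); unset fields
#'   take the pipeline defaults.
#' @return Data frame of findings with columns `level` (`"error"` /
#'   `"warning"`), `stage`, `message`. Zero rows = clean.
#' @export
validate_config <- function(config) {
  cfg <- load_config(config)
  findings <- list()
  add <- function(level, stage, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, stage = stage, message = msg, stringsAsFactors = FALSE)
  }
  unknown <- setdiff(toupper(cfg$sets), channel_set_names())
  if (length(unknown) > 0L) {
    add("error", "mmse", sprintf("unknown channel set(s): %s",
                                 paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    add("error", "input", "no input recordings and no simulate block")
  }
  p <- 4L
  m <- max(cfg$mmse$M)
  n_embed <- m * max(cfg$mmse$tau)
  n_coarse <- floor(cfg$epoch$length / cfg$mmse$eps_max)
  if (n_coarse <= n_embed) {
    add("error", "mmse",
        sprintf("coarsest scale leaves %d samples, too few to embed (need > %d)",
                n_coarse, n_embed))
  } else if (n_coarse < p * 10^m) {
    add("warning", "mmse",
        sprintf("coarsest scale leaves %d samples, below the p*10^m guideline of %d",
                n_coarse, p * 10^m))
  }
  if (length(findings) == 0L) {
    return(data.frame(level = character(0), stage = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

simulate_stage <- function(cfg, dirs, logf) {
  sim <- cfg$simulate
  n <- sim$n_subjects %||% 20L
  labels <- sim$channel_labels %||% unique(toupper(unlist(channel_sets())))
  labels <- normalize_labels(labels)
  n_samples <- sim$n_samples %||% (2L * (cfg$epoch$length %||% 10240))
  pw_range <- sim$pink_weight_range %||% c(0.15, 0.95)
  pw <- seq(pw_range[1], pw_range[2], length.out = n)
  ids <- sprintf("S%03d", seq_len(n))
  specs <- lapply(seq_len(n), function(i) {
    signal_spec(n_channels = length(labels), n_samples = n_samples,
                sampling_rate = sim$sampling_rate %||% 256,
                pink_weight = pw[i], alpha_amp = sim$alpha_amp %||% 0.5,
                seed = derive_seed(cfg$seed, 100L + i))
  })
  names(specs) <- ids
  cohort <- generate_end_to_end_cohort(specs)
  scores <- generate_test_scores(cohort$gf, seed = derive_seed(cfg$seed, 7L))
  for (id in ids) {
    rec <- cohort$recordings[[id]]
    rec$channel_labels <- labels
    rownames(rec$data) <- labels
    cohort$recordings[[id]] <- rec
    write_recording(rec, file.path(dirs$recordings, paste0(id, ".tsv")))
  }
  cohort_df <- cbind(data.frame(subject_id = ids,
                                sex = rep(c("M", "W"), length.out = n),
                                true_gf = as.numeric(cohort$gf),
                                stringsAsFactors = FALSE),
                     scores)
  write.csv(cohort_df, file.path(dirs$run, "cohort.csv"), row.names = FALSE)
  logf("simulate: %d subjects, %d channels x %d samples", n, length(labels),
       n_samples)
  list(recordings = cohort$recordings, cohort = cohort_df)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> epoch extraction -> entropy profiles ->
#' feature assembly -> gf factor extraction -> group PLSR, writing every
#' intermediate artifact, a resolved-config snapshot, a log and output
#' checksums into the run directory. Reruns with an identical
#' configuration reproduce identical outputs.
#'
#' @param config Configuration list or path to a YAML/JSON file. Main
#'   fields: `out_dir`, `seed`, `simulate` (e.g. `n_subjects`,
#'   `n_samples`), `input` (`recordings` dir and `cohort` csv), `epoch`
#'   (`length`, `amp_threshold`), `mmse` (`M`, `tau`, `r`, `eps_max`,
#'   `variant`), `sets`, `groups`, `plsr` (`ncomp`, `selector`, `n_boot`,
#'   `n_perm`, ...).
#' @return Invisibly, a list with the run directory, the feature table
#'   and one `complexity_plsr` fit per group.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  findings <- validate_config(cfg)
  if (any(findings$level == "error")) {
    stopf("config error: %s", paste(findings$message[findings$level == "error"],
                                    collapse = "; "))
  }
  for (w in findings$message[findings$level == "warning"]) warnf("%s", w)

  dirs <- list(run = cfg$out_dir, recordings = file.path(cfg$out_dir, "recordings"))
  dir.create(dirs$recordings, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dirs$run, "log.txt")
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  stage <- "input"
  result <- tryCatch({
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      sim <- simulate_stage(cfg, dirs, logf)
      recordings <- sim$recordings
      cohort <- sim$cohort
    } else {
      paths <- cfg$input$recordings
      if (length(paths) == 1L && dir.exists(paths)) {
        paths <- list.files(paths, full.names = TRUE)
      }
      recordings <- lapply(paths, read_recording)
      names(recordings) <- vapply(recordings, function(r) r$subject_id, "")
      cohort <- read.csv(cfg$input$cohort, stringsAsFactors = FALSE)
      logf("input: %d recordings read", length(recordings))
    }

    stage <- "epochs"
    params <- mmse_params(M = cfg$mmse$M, tau = cfg$mmse$tau, r = cfg$mmse$r,
                          eps_max = cfg$mmse$eps_max,
                          variant = cfg$mmse$variant)
    sets <- toupper(cfg$sets)
    stage <- "mmse"
    prof_rows <- list()
    profiles <- list()
    for (id in names(recordings)) {
      eps <- extract_epochs(recordings[[id]], cfg$epoch$length,
                            cfg$epoch$amp_threshold)
      logf("epochs %s: %d kept, %d rejected", id, length(eps),
           attr(eps, "n_rejected"))
      profiles[[id]] <- list()
      for (st in sets) {
        sub_eps <- lapply(eps, select_channel_set, set_def = st)
        prof <- suppressWarnings(
          subject_profile(sub_eps, params, channel_set = st, subject_id = id))
        profiles[[id]][[st]] <- prof
        prof_rows[[paste(id, st)]] <- data.frame(
          subject_id = id, set = st, scale = seq_along(prof),
          value = as.numeric(prof), n_epochs = length(sub_eps),
          stringsAsFactors = FALSE)
      }
    }
    prof_df <- do.call(rbind, prof_rows)
    write.csv(prof_df, file.path(dirs$run, "profiles.csv"), row.names = FALSE)

    stage <- "gf"
    battery <- cohort[, c("RAPM", "CFT3", "Paper", "Analogies", "Number",
                          "Pattern")]
    gf_res <- extract_gf_factor(battery)
    gf <- stats::setNames(gf_res$scores, cohort$subject_id)
    logf("gf: first factor explains %.1f%% (eigenvalue %.2f)",
         gf_res$explained_variance_pct, gf_res$eigenvalue)

    stage <- "features"
    sex <- stats::setNames(cohort$sex, cohort$subject_id)
    features <- assemble_features(profiles, gf, sex)
    write_feature_table(features, file.path(dirs$run, "features.csv"))
    logf("features: %d subjects x %d predictors", nrow(features),
         length(feature_names()))

    stage <- "plsr"
    fits <- list()
    for (g in cfg$groups) {
      fit <- run_group_analysis(features, group = g,
                                ncomp = cfg$plsr$ncomp,
                                selector = cfg$plsr$selector,
                                max_components = cfg$plsr$max_components,
                                n_boot = cfg$plsr$n_boot,
                                n_perm = cfg$plsr$n_perm,
                                alpha = cfg$plsr$alpha,
                                folds = cfg$plsr$folds,
                                seed = derive_seed(cfg$seed, 500L))
      fits[[g]] <- fit
      rep_df <- as.data.frame(fit$relevance)
      write.csv(rep_df, file.path(dirs$run, sprintf("report_%s.csv", g)),
                row.names = FALSE)
      logf("plsr %s: n = %d, ncomp = %d, %d relevant", g, fit$n, fit$ncomp,
           sum(fit$relevance$relevant))
    }
    list(features = features, fits = fits, gf = gf_res)
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("ABORT at stage %s: %s", stage,
                                    conditionMessage(e))), log_path)
    stopf("pipeline aborted at stage '%s': %s", stage, conditionMessage(e))
  })

  jsonlite::write_json(cfg, file.path(dirs$run, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # checksums cover the data artifacts; the config snapshot and log carry
  # run-specific paths and are excluded
  outputs <- list.files(dirs$run, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in%
                       c("checksums.txt", "log.txt", "resolved_config.json")]
  sums <- tools::md5sum(sort(outputs))
  writeLines(sprintf("%s  %s", sums,
                     substring(names(sums), nchar(dirs$run) + 2L)),
             file.path(dirs$run, "checksums.txt"))
  writeLines(log_lines, log_path)
  invisible(c(list(run_dir = dirs$run), result))
}
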