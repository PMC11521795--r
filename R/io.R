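# File formats and session bundles: CSV tables, YAML configuration,
# JSON manifests. All tables are UTF-8 CSV with a "." decimal separator
# and a schema-version header comment for diffability.

SCHEMA_VERSION <- "striatnet-schema-v1"

write_schema_csv <- function(df, path) {
  readr::write_lines(paste0("# ", SCHEMA_VERSION), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

read_schema_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a session bundle to a directory
#'
#' Writes `spikes.csv` (`session_id`, `unit_id`, `time_s`), `zones.csv`
#' (`time_s`, `zone_id`), `units.csv` (`unit_id`, `log_rate`, `pv_us`,
#' `w_us`) and `manifest.json`.
#'
#' @param bundle a `"session_bundle"` (see [simulate_session()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spikes <- bundle$spikes
  spikes$session_id <- bundle$session_id
  write_schema_csv(spikes[, c("session_id", "unit_id", "time_s")],
                   file.path(dir, "spikes.csv"))
  write_schema_csv(bundle$zones, file.path(dir, "zones.csv"))
  write_schema_csv(bundle$units[, c("unit_id", "log_rate", "pv_us", "w_us")],
                   file.path(dir, "units.csv"))
  manifest <- list(
    session_id = bundle$session_id, duration = bundle$duration,
    stage = bundle$stage, seed = bundle$config$seed,
    trials = bundle$manifest$trials,
    unit_types = bundle$manifest$unit_types,
    truly_modulated = bundle$manifest$truly_modulated
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load and validate a session bundle from a directory
#'
#' Schema violations (missing columns, unknown zone ids, unit ids in the
#' spike table absent from the feature table) raise errors listing every
#' failure; unsorted spike times are auto-sorted with a warning.
#'
#' @param dir directory holding `spikes.csv`, `zones.csv`, `units.csv`
#'   and optionally `manifest.json`.
#' @param taxonomy path taxonomy used to validate zone ids.
#' @return a `"session_bundle"` list.
#' @export
load_session_bundle <- function(dir, taxonomy = path_taxonomy()) {
  need <- c("spikes.csv", "zones.csv", "units.csv")
  missing_f <- need[!file.exists(file.path(dir, need))]
  if (length(missing_f) > 0) {
    abort(paste0("missing bundle files: ", paste(missing_f, collapse = ", ")))
  }
  spikes <- read_schema_csv(file.path(dir, "spikes.csv"))
  zones <- read_schema_csv(file.path(dir, "zones.csv"))
  units <- read_schema_csv(file.path(dir, "units.csv"))
  problems <- character(0)
  check_cols <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      problems <<- c(problems, sprintf("%s lacks column(s): %s", name,
                                       paste(miss, collapse = ", ")))
    }
  }
  check_cols(spikes, c("session_id", "unit_id", "time_s"), "spikes.csv")
  check_cols(zones, c("time_s", "zone_id"), "zones.csv")
  check_cols(units, c("unit_id", "log_rate", "pv_us", "w_us"), "units.csv")
  if (length(problems) > 0) abort(paste(problems, collapse = "\n"))
  known <- unique(unlist(taxonomy$nodes))
  bad <- setdiff(unique(zones$zone_id), known)
  if (length(bad) > 0) {
    abort(paste0("unknown zone id(s): ", paste(bad, collapse = ", ")))
  }
  orphan <- setdiff(unique(spikes$unit_id), units$unit_id)
  if (length(orphan) > 0) {
    abort(paste0("spike unit id(s) missing from units table: ",
                 paste(orphan, collapse = ", ")))
  }
  if (is.unsorted(spikes$time_s)) {
    warn("spike times were not sorted; sorting")
    spikes <- dplyr::arrange(spikes, .data$time_s)
  }
  manifest <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  duration <- if (!is.null(manifest$duration)) manifest$duration else
    max(spikes$time_s, zones$time_s)
  structure(
    list(
      session_id = spikes$session_id[1] %||% "session",
      zones = zones[, c("time_s", "zone_id")],
      spikes = spikes[, c("unit_id", "time_s")],
      units = units, duration = duration,
      stage = manifest$stage, config = NULL, manifest = manifest
    ),
    class = "session_bundle"
  )
}

#' Run the analysis pipeline on a session bundle
#'
#' Executes the requested stages in dependency order (behavior ->
#' coding detection -> population activity -> unit classification ->
#' synchrony -> network models -> decoding) and writes one CSV/JSON
#' output per stage plus a run manifest (config hash and seeds).
#' Dependency violations are reported before any computation.
#'
#' @param bundle a `"session_bundle"`.
#' @param stages character subset of `c("behavior", "coding",
#'   "population", "classify", "sync", "networks", "decoding")`.
#' @param out_dir output directory.
#' @param seed master seed for the stochastic stages.
#' @param n_perm permutations for the synchrony stage.
#' @return (invisibly) a named list of the in-memory stage results.
#' @export
run_pipeline <- function(bundle,
                         stages = c("behavior", "coding", "population",
                                    "classify", "sync", "networks",
                                    "decoding"),
                         out_dir, seed = 1L, n_perm = 2000) {
  all_stages <- c("behavior", "coding", "population", "classify", "sync",
                  "networks", "decoding")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(
    coding = "behavior", population = "behavior", sync = "behavior",
    networks = "behavior", decoding = c("behavior", "coding", "networks")
  )
  for (s in stages) {
    lacking <- setdiff(deps[[s]], stages)
    if (length(lacking) > 0) {
      abort(sprintf("stage `%s` requires stage(s): %s", s,
                    paste(lacking, collapse = ", ")))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  unit_ids <- sort(unique(bundle$units$unit_id))
  spike_list <- split(bundle$spikes$time_s,
                      factor(bundle$spikes$unit_id, levels = unit_ids))

  frames <- behavior_frames(bundle$zones, bundle$duration)
  if ("behavior" %in% stages) {
    res$traversals <- frames$traversals
    res$performance <- compute_performance(frames$traversals,
                                           bundle$duration)
    write_schema_csv(frames$traversals, file.path(out_dir, "paths.csv"))
    write_schema_csv(frames$events, file.path(out_dir, "events.csv"))
    write_schema_csv(res$performance, file.path(out_dir, "performance.csv"))
  }
  if ("coding" %in% stages) {
    res$coding <- dplyr::bind_rows(lapply(
      c("task_event", "left_right", "full_path"),
      function(m) {
        tryCatch(
          detect_coding_units(bundle$spikes, frames, m,
                              unit_ids = unit_ids),
          error = function(e) NULL
        )
      }
    ))
    write_schema_csv(res$coding, file.path(out_dir, "coding.csv"))
  }
  if ("population" %in% stages) {
    profs <- dplyr::bind_rows(lapply(seq_along(unit_ids), function(j) {
      pr <- zscore_profile(bin_firing_rates(spike_list[[j]], frames))
      if (isTRUE(attr(pr, "excluded"))) return(NULL)
      pr$unit_id <- unit_ids[j]
      pr$group <- paste0("stage", bundle$stage %||% 0)
      pr
    }))
    res$zscores <- profs
    write_schema_csv(profs, file.path(out_dir, "zscores.csv"))
    if (nrow(profs) > 0) {
      curves <- population_curves(profs[!is.na(profs$z), ])
      res$curves <- curves
      write_schema_csv(tibble::as_tibble(curves),
                       file.path(out_dir, "curves.csv"))
      ent <- zscore_entropy(profs$z[!is.na(profs$z)])
      res$entropy <- ent
      write_schema_csv(glance(ent), file.path(out_dir, "entropy.csv"))
    }
  }
  if ("classify" %in% stages) {
    res$unit_types <- classify_units(bundle$units)
    write_schema_csv(tibble::as_tibble(res$unit_types),
                     file.path(out_dir, "unit_types.csv"))
  }
  if ("sync" %in% stages) {
    trials <- frames$events[frames$events$event %in% c("A", "B"), ]
    pairs <- utils::combn(seq_along(unit_ids), 2)
    sync <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(q) {
      i <- pairs[1, q]
      j <- pairs[2, q]
      dplyr::bind_rows(lapply(c("A", "B"), function(ev) {
        tw <- trials[trials$event == ev, c("start", "end")]
        if (nrow(tw) < 2) return(NULL)
        out <- test_synchrony(spike_list[[i]], spike_list[[j]], tw,
                              n_perm = n_perm,
                              seed = child_seed(seed, 1000L + q))
        out$unit_a <- unit_ids[i]
        out$unit_b <- unit_ids[j]
        out$intersection <- ev
        out
      }))
    }))
    res$sync <- sync
    write_schema_csv(sync, file.path(out_dir, "sync_pairs.csv"))
    if (nrow(sync) > 0) {
      res$sync_ks <- sync_ks_tests(
        sync[, c("intersection", "p_value")],
        group_cols = "intersection", region_col = NULL
      )
      write_schema_csv(res$sync_ks, file.path(out_dir, "sync_ks.csv"))
    }
  }
  if ("networks" %in% stages) {
    ci <- build_condition_intervals(frames$traversals)
    keep <- names(which(table(ci$condition) >= 1))
    ci <- ci[ci$condition %in% keep, , drop = FALSE]
    res$network <- fit_hawkes_network(spike_list, ci)
    edges <- interaction_graph(interaction_strengths(res$network))
    res$edges <- edges
    write_schema_csv(tibble::as_tibble(edges),
                     file.path(out_dir, "edges.csv"))
    nets <- lapply(res$network$conditions, function(ck) {
      list(mu = ck$mu, a = ck$a, duration = ck$duration)
    })
    jsonlite::write_json(
      list(threshold = attr(edges, "threshold"), conditions = nets),
      file.path(out_dir, "networks.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if ("decoding" %in% stages) {
    full_path_coding <- res$coding[res$coding$mode == "full_path", ,
                                   drop = FALSE]
    elig <- session_eligibility(frames$traversals, full_path_coding)
    if (elig$eligible) {
      dec <- dplyr::bind_rows(lapply(c("poisson", "hawkes"), function(m) {
        r <- session_decoding_power(
          spike_list, frames$traversals, model = m,
          seed = child_seed(seed, 7L),
          session_duration = bundle$duration
        )
        glance(r)
      }))
      dec$eligible <- TRUE
      dec$reasons <- ""
    } else {
      dec <- tibble::tibble(
        model = c("poisson", "hawkes"), power = NA_real_,
        reference = NA_real_, n_paths = NA_integer_,
        n_units = NA_integer_, n_test_trials = NA_integer_,
        mean_rate = NA_real_, eligible = FALSE,
        reasons = paste(elig$reasons, collapse = "; ")
      )
    }
    res$decoding <- dec
    write_schema_csv(dec, file.path(out_dir, "decoding.csv"))
  }
  run_manifest <- list(
    schema = SCHEMA_VERSION, seed = seed, stages = stages,
    session_id = bundle$session_id,
    config_hash = rlang::hash(bundle$manifest %||% bundle$zones),
    timestamp = "run"
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
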