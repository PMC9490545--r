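#' Derive per-stage sub-seeds from one global seed
#'
#' Expands a single integer seed into independent stage seeds so any stage
#' can be rerun with stable randomness.
#'
#' @param seed Integer.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full audit-workflow pipeline
#'
#' Orchestrates simulate -> extract -> calibrate -> impute -> validate ->
#' match -> evaluate. Each stage writes its outputs under `out_dir` and a
#' manifest records inputs, seeds, row counts and MD5 checksums,
#' hash-chained stage to stage; a rerun with the same config and seed is
#' byte-identical. On stage failure a `FAILED` marker naming the stage is
#' left next to the partial outputs.
#'
#' @param config A [sim_config()], a list of overrides, or a path to a
#'   YAML/JSON config file.
#' @param seed Global integer seed, expanded into per-stage sub-seeds.
#' @param out_dir Output directory (created if needed).
#' @param two_level Attempt physician-level matching before patient-level
#'   matching (skipped, with a note, when there are too few physicians on
#'   either side).
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir = "auditflow-out",
                         two_level = TRUE) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 8L)
  manifest <- list(seed = as.integer(seed), stages = list())
  prev_hash <- ""
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste("FAILED at stage:", name, "--", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    sums <- as.character(tools::md5sum(file.path(out_dir, res$outputs)))
    entry <- list(stage = name, outputs = res$outputs, md5 = sums,
                  rows = res$rows, prev = prev_hash)
    prev_hash <<- substr(digest_chain(c(prev_hash, sums)), 1, 16)
    entry$hash <- prev_hash
    manifest$stages[[name]] <<- entry
    res$value
  }

  sim <- stage("simulate", function() {
    cfg <- config; cfg$seed <- seeds[1]
    s <- simulate_clinic(cfg)
    write_audit_log(s$events, file.path(out_dir, "audit_log.csv"))
    write_time_motion(s$time_motion, file.path(out_dir, "time_motion.csv"))
    write_location_map(s$location_map, file.path(out_dir, "location_map.csv"))
    write_encounters(s$encounters, file.path(out_dir, "encounters.csv"))
    utils::write.csv(s$patients, file.path(out_dir, "patients.csv"), row.names = FALSE)
    utils::write.csv(s$physicians, file.path(out_dir, "physicians.csv"), row.names = FALSE)
    write_truth(s$truth, file.path(out_dir, "truth.jsonl"))
    list(value = s,
         outputs = c("audit_log.csv", "time_motion.csv", "location_map.csv",
                     "encounters.csv", "patients.csv", "physicians.csv",
                     "truth.jsonl"),
         rows = list(events = nrow(s$events), encounters = nrow(s$encounters)))
  })

  points <- stage("extract", function() {
    p <- derive_workflow_points(sim$events, sim$location_map)
    write_points(p, file.path(out_dir, "points_audit.csv"))
    utils::write.csv(attr(p, "quality"), file.path(out_dir, "extract_quality.csv"),
                     row.names = FALSE)
    list(value = p, outputs = c("points_audit.csv", "extract_quality.csv"),
         rows = list(points = nrow(p), flagged = nrow(attr(p, "quality"))))
  })

  model <- stage("calibrate", function() {
    m <- calibrate_blackholes(sim$time_motion, points, sim$encounters,
                              sim$patients)
    write_blackhole_model(m, file.path(out_dir, "blackhole_model.json"))
    list(value = m, outputs = "blackhole_model.json",
         rows = list(intervals = length(m$intervals)))
  })

  imp <- stage("impute", function() {
    p2 <- impute_points(points, model, seed = seeds[2])
    write_points(p2, file.path(out_dir, "points_imputed.csv"))
    meas <- compute_measures(p2, sim$events, sim$location_map)
    utils::write.csv(meas, file.path(out_dir, "measures.csv"), row.names = FALSE)
    list(value = list(points = p2, measures = meas),
         outputs = c("points_imputed.csv", "measures.csv"),
         rows = list(points = nrow(p2), measures = nrow(meas),
                     clipped = attr(p2, "n_clipped")))
  })

  stage("validate", function() {
    tab <- discrepancy_table(sim$time_motion, points)
    flags <- flag_outliers(attr(tab, "differences"), k = 2)
    utils::write.csv(tab, file.path(out_dir, "validation_table.csv"),
                     row.names = FALSE)
    utils::write.csv(flags, file.path(out_dir, "validation_flags.csv"),
                     row.names = FALSE)
    list(value = tab, outputs = c("validation_table.csv", "validation_flags.csv"),
         rows = list(labels = nrow(tab), flagged = nrow(flags)))
  })

  matched <- stage("match", function() {
    enc <- sim$encounters
    case_pat <- unique(enc$patient_id[enc$exposure])
    pool_phys <- unique(enc$physician_id)
    note <- ""
    if (two_level) {
      case_phys <- unique(enc$physician_id[enc$exposure])
      ctl_phys <- setdiff(pool_phys, case_phys)
      if (length(case_phys) >= 2 && length(ctl_phys) >= 2) {
        ps <- summarize_physicians(enc, sim$patients, sim$physicians)
        feats <- ps[, setdiff(names(ps), "physician_id"), drop = FALSE]
        feats$practice_internal <- as.numeric(ps$practice_type == "internal")
        feats$practice_type <- NULL
        sc <- fit_propensity(feats, ps$physician_id %in% case_phys)
        names(sc) <- ps$physician_id
        # physician panels are few: a permissive caliper keeps the level
        # usable while still ordering matches by panel similarity
        pm <- greedy_match(sc[case_phys], sc[ctl_phys], ratio = 1, caliper = 1)
        keep_phys <- unique(c(pm$pairs$case_id, pm$pairs$control_id))
        if (length(keep_phys) >= 2) pool_phys <- keep_phys
        utils::write.csv(pm$pairs, file.path(out_dir, "physician_pairs.csv"),
                         row.names = FALSE)
      } else {
        note <- "physician-level matching skipped: too few physicians per arm"
        utils::write.csv(data.frame(), file.path(out_dir, "physician_pairs.csv"),
                         row.names = FALSE)
      }
    } else {
      utils::write.csv(data.frame(), file.path(out_dir, "physician_pairs.csv"),
                       row.names = FALSE)
    }
    enc_pool <- enc[enc$physician_id %in% pool_phys, , drop = FALSE]
    su <- summarize_patients(enc_pool, sim$patients)
    feats <- su[, c("age", "female", "hispanic", "pct_appt15", "pct_appt30",
                    "pct_los3", "pct_los4", "pct_dx_dm", "pct_dx_htn",
                    "pct_dx_dyslip"), drop = FALSE]
    is_case <- su$patient_id %in% case_pat
    if (sum(is_case) < 2 || sum(!is_case) < 2) {
      stop("too few case or control patients for matching")
    }
    sc <- fit_propensity(feats, is_case)
    names(sc) <- su$patient_id
    mc <- greedy_match(sc[su$patient_id[is_case]],
                       sc[su$patient_id[!is_case]], ratio = 1)
    utils::write.csv(mc$pairs, file.path(out_dir, "patient_pairs.csv"),
                     row.names = FALSE)
    bt <- balance_table(cbind(id = su$patient_id, feats),
                        su$patient_id[is_case], su$patient_id[!is_case],
                        mc, covariates = names(feats))
    utils::write.csv(bt, file.path(out_dir, "balance.csv"), row.names = FALSE)
    list(value = mc,
         outputs = c("physician_pairs.csv", "patient_pairs.csv", "balance.csv"),
         rows = list(pairs = nrow(mc$pairs), unmatched = length(mc$unmatched),
                     note = note))
  })

  stage("evaluate", function() {
    enc <- eligible_encounters(sim$encounters, matched = matched)
    # case arm: encounters where the tool was launched; control arm: the
    # matched control patients' (unexposed) eligible encounters
    is_case_pat <- enc$patient_id %in% matched$pairs$case_id
    enc <- enc[(is_case_pat & enc$exposure) | (!is_case_pat & !enc$exposure), ,
               drop = FALSE]
    eff <- list()
    for (st in c("none", "appt")) {
      eff[[st]] <- stratified_effects(imp$measures, enc, matched, strata = st,
                                      methods = c("mixed", "ttest"))
    }
    eff <- do.call(rbind, eff)
    rownames(eff) <- NULL
    utils::write.csv(eff, file.path(out_dir, "effects.csv"), row.names = FALSE)
    list(value = eff, outputs = "effects.csv", rows = list(rows = nrow(eff)))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# order-sensitive fold of md5 strings into one hash
digest_chain <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  as.character(tools::md5sum(f))
}

#' Read a pipeline config file (YAML or JSON)
#' @param path File path ending in .yaml/.yml/.json.
#' @return A [sim_config()] object.
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, lst)
}
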