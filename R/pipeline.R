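# One-call analysis battery over a trajectory set, and condition comparison.

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config[sort(names(config))], tf)
  unname(tools::md5sum(tf))
}

#' Build a pipeline run configuration
#'
#' @param inputs Character vector of multi-model PDB paths (replicas), or a
#'   list of in-memory trajectories.
#' @param chain_a,chain_b Monomer chain ids; set `chain_b = NULL` for a
#'   single-monomer run (contact and contact-surface stages are skipped).
#' @param window `c(t_start, t_end)` in ps, or `NULL` to keep all frames.
#' @param stride Sampling stride (ps) used with `window`.
#' @param cutoff Contact cutoff (nm).
#' @param atom_policy `"all"` or `"heavy"` for contact distances.
#' @param regions Named list of `c(first, last)` residue ranges on
#'   `chain_a`; defaults to the hairpin (31-62), alpha-3 (57-62) and
#'   alpha-4 (84-87) landmarks.
#' @param mixture `list(k, seed, n_starts)` for the RG decomposition.
#' @param contact_surface_frames How many (evenly spaced) frames get the
#'   SAS-based contact surface (it is the slow stage); 0 disables.
#' @param outdir Output directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, chain_a = "A", chain_b = "B", window = NULL,
                       stride = 50, cutoff = 0.28, atom_policy = "all",
                       regions = list(hairpin = c(31L, 62L),
                                      alpha3 = c(57L, 62L),
                                      alpha4 = c(84L, 87L)),
                       mixture = list(k = 2L, seed = 1L, n_starts = 5L),
                       contact_surface_frames = 5L,
                       outdir = NULL) {
  if (is.character(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "))
  }
  structure(list(inputs = inputs, chain_a = chain_a, chain_b = chain_b,
                 window = window, stride = stride, cutoff = cutoff,
                 atom_policy = atom_policy, regions = regions,
                 mixture = mixture,
                 contact_surface_frames = as.integer(contact_surface_frames),
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$regions <- lapply(y$regions, unlist)
  do.call(run_config, y)
}

.pool_trajectories <- function(trajs) {
  if (length(trajs) == 1L) return(trajs[[1]])
  top <- trajs[[1]]$topology
  for (t2 in trajs[-1]) {
    if (!identical(t2$topology$name, top$name) ||
        !identical(t2$topology$resid, top$resid)) {
      stop("replica topologies differ; cannot pool")
    }
  }
  coords <- array(NA_real_, c(nrow(top), 3L,
                              sum(vapply(trajs, n_frames, integer(1)))))
  times <- numeric(0); k <- 0L
  for (tr in trajs) {
    nf <- n_frames(tr)
    coords[, , k + seq_len(nf)] <- tr$coords
    times <- c(times, tr$times)
    k <- k + nf
  }
  # pooled replicas form one ensemble; times are kept per-replica but the
  # pooled object no longer claims monotonicity, so re-index
  trajectory(top, coords, times = seq(0, by = 1, length.out = k))
}

#' Run the full analysis battery
#'
#' Stages, in order: frame selection, contact probability + map + interface
#' table, contact surface, RG series + Gaussian mixture + state
#' classification, RMSF, region-COM distances, secondary-structure profile,
#' Ramachandran summary. Multi-replica inputs are pooled into one ensemble
#' before the ensemble statistics. Every output table carries the config
#' hash. Stage failures are rethrown with the stage name.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @param verbose Log stage progress via `message()`.
#' @return An `analysis_report` list.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  hash <- .config_hash(unclass(config))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  trajs <- stage("load", {
    if (is.character(config$inputs)) {
      lapply(config$inputs, read_multimodel_pdb)
    } else config$inputs
  })
  if (!is.null(config$window)) {
    trajs <- stage("slice", lapply(trajs, select_frames,
                                   t_start = config$window[1],
                                   t_end = config$window[2],
                                   stride = config$stride))
  }
  pooled <- stage("pool", .pool_trajectories(trajs))
  say("pooled ensemble: %d frames, %d atoms", n_frames(pooled), n_atoms(pooled))

  chain_a <- config$chain_a
  dimeric <- !is.null(config$chain_b) &&
    config$chain_b %in% pooled$topology$chain

  contacts <- cmap <- iface <- cs <- NULL
  if (dimeric) {
    contacts <- stage("contacts", contact_probability(
      pooled, chain_a, config$chain_b, cutoff = config$cutoff,
      atom_policy = config$atom_policy))
    cmap <- stage("contact_map", contact_map(
      pooled, chain_a, config$chain_b, cutoff = config$cutoff,
      atom_policy = config$atom_policy))
    iface <- stage("interface_table", interface_table(contacts, cmap))
    if (config$contact_surface_frames > 0) {
      cs <- stage("contact_surface", {
        idx <- unique(round(seq(1, n_frames(pooled),
                                length.out = config$contact_surface_frames)))
        vals <- vapply(idx, function(f) {
          contact_surface_area(get_frame(pooled, f), chain_a, config$chain_b)
        }, numeric(1))
        data.frame(frame = idx, cs_nm2 = vals)
      })
    }
  } else {
    say("single-monomer run: contact and contact-surface stages skipped")
  }

  sel_a <- which(pooled$topology$chain == chain_a)
  rg <- stage("rg", rg_series(pooled, selection = sel_a))
  rgfit <- stage("rg_mixture", {
    k <- config$mixture$k
    if (k >= 2 && length(rg$values) < 10 * k) {
      say("too few frames for a %d-component mixture; fitting k = 1", k)
      k <- 1L
    }
    if (k >= 2) {
      fit_gaussian_mixture(rg$values, k = k, seed = config$mixture$seed,
                           n_starts = config$mixture$n_starts)
    } else fit_gaussian(rg$values)
  })
  states <- NULL
  if (rgfit$k >= 2) {
    states <- stage("states", classify_states(
      rg, open_center = rgfit$means[1], closed_center = rgfit$means[2],
      band = min(rgfit$sds[1], rgfit$sds[2],
                 (rgfit$means[1] - rgfit$means[2]) / 2.001)))
  }

  hairpin_rng <- config$regions$hairpin
  core_sel <- which(pooled$topology$chain == chain_a &
                      pooled$topology$name == "CA" &
                      !(pooled$topology$resid >= hairpin_rng[1] &
                          pooled$topology$resid <= hairpin_rng[2]))
  rmsf <- stage("rmsf", rmsf_profile(pooled, fit_selection = core_sel,
                                     report_atoms = which(
                                       pooled$topology$chain == chain_a &
                                         pooled$topology$name == "CA")))
  comdist <- stage("comdist", {
    out <- list()
    for (nm in setdiff(names(config$regions), "hairpin")) {
      rng <- config$regions[[nm]]
      out[[nm]] <- region_com_distance(
        pooled, region_spec(nm, chain_a, rng[1], rng[2]))
    }
    out
  })
  ssprof <- stage("ss_profile", ss_profile(pooled, chain_a))
  rama <- stage("ramachandran", {
    nfr <- n_frames(pooled)
    idx <- unique(round(seq(1, nfr, length.out = min(nfr, 50))))
    recs <- do.call(rbind, lapply(idx, function(f) {
      backbone_dihedrals(get_frame(pooled, f), chain_a)
    }))
    ramachandran_classify(recs)
  })

  report <- structure(list(
    contacts = contacts, contact_map = cmap, interface = iface,
    contact_surface = cs, rg = rg, rg_fit = rgfit, states = states,
    rmsf = rmsf, comdist = comdist, ss_profile = ssprof,
    rama_favored = rama$favored_fraction,
    meta = list(version = as.character(utils::packageVersion("dimerlens")),
                config = config, config_hash = hash, log = log)),
    class = "analysis_report")
  if (!is.null(config$outdir)) .write_report(report, config$outdir)
  report
}

.write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- report$meta$config_hash
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    df$config_hash <- hash
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  if (!is.null(report$contacts)) {
    wr(report$contacts$a, "contacts_A.csv")
    wr(report$contacts$b, "contacts_B.csv")
    utils::write.csv(as.data.frame(report$contact_map$freq),
                     file.path(outdir, "contact_map.csv"))
    wr(report$interface, "interface.csv")
  }
  if (!is.null(report$contact_surface)) wr(report$contact_surface,
                                           "contact_surface.csv")
  wr(as.data.frame(report$rg), "rg.csv")
  jsonlite::write_json(
    c(unclass(report$rg_fit), list(config_hash = hash)),
    file.path(outdir, "rg_fit.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$states)) {
    wr(data.frame(time_ps = report$states$times,
                  state = report$states$labels), "states.csv")
  }
  wr(as.data.frame(report$rmsf), "rmsf.csv")
  for (nm in names(report$comdist)) {
    wr(as.data.frame(report$comdist[[nm]]), sprintf("comdist_%s.csv", nm))
  }
  wr(as.data.frame(report$ss_profile), "ss_profile.csv")
  writeLines(report$meta$log, file.path(outdir, "run.log"))
  jsonlite::write_json(list(version = report$meta$version,
                            config_hash = hash,
                            rama_favored = report$rama_favored),
                       file.path(outdir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

#' Compare two analysis reports (e.g. wild type vs mutant)
#'
#' @param report_a,report_b `analysis_report` objects. Residue vocabularies
#'   are aligned on their intersection, with a warning if they differ.
#' @return List of difference tables: `contact_delta` (ordered by
#'   descending |delta|), `rmsf_delta`, `helix_delta`, `rg_fit_delta`.
#' @export
compare_conditions <- function(report_a, report_b) {
  join <- function(da, db, value, by = "resid") {
    if (is.null(da) || is.null(db)) return(NULL)
    common <- intersect(da[[by]], db[[by]])
    if (length(common) < max(nrow(da), nrow(db))) {
      warning("residue vocabularies differ; aligned on intersection")
    }
    da <- da[match(common, da[[by]]), ]
    db <- db[match(common, db[[by]]), ]
    out <- data.frame(resid = common, a = da[[value]], b = db[[value]],
                      delta = db[[value]] - da[[value]])
    names(out)[2:3] <- paste0(value, c("_a", "_b"))
    out
  }
  contact_delta <- NULL
  if (!is.null(report_a$contacts) && !is.null(report_b$contacts)) {
    contact_delta <- join(report_a$contacts$a, report_b$contacts$a,
                          "probability")
    contact_delta <- contact_delta[order(-abs(contact_delta$delta),
                                         contact_delta$resid), ]
    rownames(contact_delta) <- NULL
  }
  rmsf_delta <- join(as.data.frame(report_a$rmsf),
                     as.data.frame(report_b$rmsf), "rmsf")
  helix_delta <- join(as.data.frame(report_a$ss_profile),
                      as.data.frame(report_b$ss_profile), "helix")
  rg_delta <- list(means = report_b$rg_fit$means - report_a$rg_fit$means,
                   sds = report_b$rg_fit$sds - report_a$rg_fit$sds,
                   weights = report_b$rg_fit$weights - report_a$rg_fit$weights)
  list(contact_delta = contact_delta, rmsf_delta = rmsf_delta,
       helix_delta = helix_delta, rg_fit_delta = rg_delta)
}
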