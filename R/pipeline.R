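#' Run the analysis pipeline on a synthetic or loaded session
#'
#' Orchestrates the standard stage sequence — simulate (or load), single
#' cell metrics, rSLDS fit, integrator model, decoder — recording per-stage
#' status, seeds and wall time in a manifest. Stages whose dependencies
#' failed are skipped. Deterministic given (config, seed).
#'
#' @param config list with fields: `sim` (a [sim_config()]) or `raster` +
#'   `male_bouts` + `female_bouts` for pre-loaded data; `stages` character
#'   subset of c("simulate", "metrics", "rslds", "integrator", "decoder");
#'   `K`, `D` model order (defaults 1, 2); `out_dir` optional directory
#'   for CSV/JSON artifacts.
#' @param seed integer master seed.
#' @return list with `manifest` (stage records) and `results` (named list
#'   of stage outputs).
#' @export
run_pipeline <- function(config, seed = 1) {
  stages <- config$stages %||% c("simulate", "metrics", "rslds",
                                 "integrator", "decoder")
  manifest <- list(seed = seed, stages = list(),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  results <- list()
  failed <- character(0)

  record <- function(name, status, elapsed, note = NULL) {
    manifest$stages[[name]] <<- list(status = status,
                                     elapsed_s = round(elapsed, 3),
                                     note = note)
  }
  run_stage <- function(name, deps, fun) {
    if (!name %in% stages) return(invisible(NULL))
    if (any(deps %in% failed)) {
      record(name, "skipped", 0, paste("dependency failed:",
                                       paste(intersect(deps, failed),
                                             collapse = ", ")))
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e) e)
    el <- proc.time()[3] - t0
    if (inherits(out, "error")) {
      record(name, "failed", el, conditionMessage(out))
      failed <<- c(failed, name)
    } else {
      record(name, "ok", el)
      results[[name]] <<- out
    }
    invisible(NULL)
  }

  run_stage("simulate", character(0), function() {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- derive_seed(seed, cfg$seed %||% 0)
      simulate_session(cfg)
    } else if (!is.null(config$raster)) {
      list(raster = config$raster, male_bouts = config$male_bouts,
           female_bouts = config$female_bouts, latents = NULL)
    } else stop("config must provide either sim or raster")
  })
  ses <- results$simulate

  run_stage("metrics", "simulate", function() {
    achw <- achw_population(ses$raster)
    list(achw = achw, mean_achw = mean(achw, na.rm = TRUE))
  })
  run_stage("rslds", "simulate", function() {
    fit <- fit_rslds(ses$raster, K = config$K %||% 1, D = config$D %||% 2,
                     seed = derive_seed(seed, 31))
    tcs <- time_constants(fit)
    list(fit = fit, time_constants = tcs,
         la_score = line_attractor_score(tcs),
         integration = integration_dimension(fit))
  })
  run_stage("integrator", "rslds", function() {
    idim <- results$rslds$integration
    fit_input_driven_integrator(idim$raw, ses$male_bouts)
  })
  run_stage("decoder", "simulate", function() {
    acc <- filter_bouts(ses$female_bouts, group = "accept")
    res <- filter_bouts(ses$female_bouts, group = "resistance")
    if (nrow(acc) == 0 || nrow(res) == 0)
      return(list(flag = "missing a behaviour class"))
    framewise_svm_decoder(ses$raster, acc, res,
                          seed = derive_seed(seed, 41))
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(ses$male_bouts))
      write_bouts(ses$male_bouts, file.path(config$out_dir,
                                            "male_bouts.csv"))
    if (!is.null(ses$raster))
      write_raster(ses$raster, file.path(config$out_dir, "raster.csv"))
  }
  manifest$failed <- failed
  list(manifest = manifest, results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an rSLDS model to JSON
#'
#' Round-trips the full parameter set exactly (doubles written at full
#' precision).
#'
#' @param model an `rslds_model` or fit.
#' @param path output file.
#' @export
write_rslds <- function(model, path) {
  m <- as_rslds_model(model)
  enc <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else if (is.list(x)) lapply(x, enc)
    else x
  }
  obj <- list(K = m$K, D = m$D, A = enc(m$A), b = m$b, Q = enc(m$Q),
              W = if (is.null(m$W)) NULL else enc(m$W),
              R = enc(m$R), r = m$r, logPi = enc(m$logPi),
              C = enc(m$C), d = m$d, Sdiag = m$Sdiag, x0 = m$x0,
              V0 = enc(m$V0), frame_rate = m$frame_rate,
              occupancy = m$occupancy, neuron_ids = m$neuron_ids)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read an rSLDS model from JSON
#' @param path file written by [write_rslds()].
#' @return an `rslds_model`.
#' @export
read_rslds <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  dec <- function(x) {
    dm <- num(x$dim)
    matrix(num(x$data), dm[1], dm[2])
  }
  dec_list <- function(x) lapply(x, dec)
  m <- list(K = as.integer(unlist(o$K)), D = as.integer(unlist(o$D)),
            A = dec_list(o$A), b = lapply(o$b, num), Q = dec_list(o$Q),
            W = if (is.null(o$W) || length(o$W) == 0) NULL
                else dec_list(o$W),
            R = dec(o$R), r = num(o$r), logPi = dec(o$logPi),
            C = dec(o$C), d = num(o$d),
            Sdiag = num(o$Sdiag), x0 = num(o$x0),
            V0 = dec(o$V0), frame_rate = num(o$frame_rate),
            occupancy = num(o$occupancy),
            neuron_ids = if (is.null(o$neuron_ids)) NULL
                         else as.character(unlist(o$neuron_ids)))
  class(m) <- "rslds_model"
  m
}
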