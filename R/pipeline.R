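#' Run the end-to-end recording-regime pipeline
#'
#' Executes the requested stages in order — simulate the population,
#' estimate yields under the equally spaced schedules (both methods),
#' compute BLUP EBVs and ranking agreement, search for strategic regimes,
#' build the progeny-testing planning table, and derive recommended
#' sampling windows — writing every artifact as headered CSV (summaries
#' additionally as JSON) plus a manifest with MD5 checksums, the full
#' configuration and the master seed. Stage randomness flows from the
#' master seed through named substreams (`pedigree`, `population`,
#' `search`), so each stage reproduces in isolation.
#'
#' @param config a [run_config()] (or a YAML path, see
#'   [read_run_config()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage results:
#'   `population`, `estimates`, `reports`, `ebv`, `comparison`, `search`,
#'   `plan`, `windows`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, c("pedigree", "population", "search"))
  res <- list()
  artifacts <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }

  # -- simulate ---------------------------------------------------------
  ped <- synthetic_pedigree(config$n_sires, config$n_dams,
                            seed = seeds[["pedigree"]])
  scn <- scenario_effects(config$scenario)
  pop <- simulate_population(scn, config$vc, ped, L = config$L,
                             seed = seeds[["population"]])
  res$population <- pop
  if ("simulate" %in% config$stages) {
    write_pedigree_csv(ped, file.path(out_dir, "pedigree.csv"))
    artifacts <- c(artifacts, file.path(out_dir, "pedigree.csv"))
    truth <- data.frame(cow = pop$cows, true_yield = pop$true_yield,
                        pop$params,
                        K_G = pop$genetic[pop$cows, "k"],
                        B_G = pop$genetic[pop$cows, "b"],
                        C_G = pop$genetic[pop$cows, "c"])
    put(truth, "truth.csv")
    for (s in config$schedules) {
      rec <- subset_testdays(pop, standard_schedule(s, L = config$L))
      write_testday_csv(rec, file.path(out_dir, paste0("testday_", s, ".csv")))
      artifacts <- c(artifacts, file.path(out_dir, paste0("testday_", s, ".csv")))
    }
  }

  # -- estimate ---------------------------------------------------------
  if (any(c("estimate", "ebv", "plan") %in% config$stages)) {
    ests <- list(); reports <- list(); mm <- integer(0)
    for (s in config$schedules) {
      sch <- standard_schedule(s, L = config$L)
      for (meth in c("TIM", "WOOD")) {
        e <- estimate_yields(pop, sch, method = meth)
        key <- paste0(meth, "/", s)
        ests[[key]] <- e
        reports[[key]] <- score_estimates(e, pop$true_yield)
        mm[key] <- length(sch)
      }
    }
    res$estimates <- do.call(rbind, ests)
    res$reports <- reports
    res$m_per_regime <- mm
    if ("estimate" %in% config$stages) {
      put(res$estimates, "estimates.csv")
      rp <- data.frame(regime = names(reports),
                       msep = vapply(reports, `[[`, numeric(1), "msep"),
                       bias = vapply(reports, `[[`, numeric(1), "bias"),
                       sigma_delta = vapply(reports, `[[`, numeric(1), "sigma_delta"),
                       n = vapply(reports, `[[`, numeric(1), "n"))
      put(rp, "accuracy.csv")
    }
  }

  # -- ebv --------------------------------------------------------------
  if ("ebv" %in% config$stages) {
    ebv_true <- blup_ebv(pop$true_yield, ped, h2 = config$h2)
    rows <- list(data.frame(animal = ebv_true$animal, ebv = ebv_true$ebv,
                            source = "TRUE"))
    comp <- list()
    for (key in names(res$reports)) {
      eb <- blup_ebv(res$estimates[res$estimates$method == sub("/.*", "", key) &
                                     res$estimates$schedule == sub(".*/", "", key), ],
                     ped, h2 = config$h2)
      rows[[key]] <- data.frame(animal = eb$animal, ebv = eb$ebv, source = key)
      comp[[key]] <- data.frame(
        source = key,
        top_overlap = top_k_overlap(eb, ebv_true, k = config$top_k),
        ebv_correlation = ebv_correlation(eb, ebv_true))
    }
    res$ebv <- do.call(rbind, rows)
    res$comparison <- do.call(rbind, comp)
    put(res$ebv, "ebv.csv")
    put(res$comparison, "ebv_comparison.csv")
  }

  # -- search -----------------------------------------------------------
  if (any(c("search", "recommend") %in% config$stages)) {
    sr <- run_search(pop, m = config$m, loops = config$loops,
                     min_coverage = config$coverage,
                     seed = seeds[["search"]],
                     track_ebv = "recommend" %in% config$stages,
                     h2 = config$h2, k = config$top_k)
    res$search <- sr
    if ("search" %in% config$stages) {
      put(sr$trace, "search_trace.csv")
      summ <- list(
        m = sr$m,
        pool_sizes = vapply(sr$loops, function(l) length(l$pool), integer(1)),
        median_msep = vapply(sr$loops, `[[`, numeric(1), "median_msep"),
        best = sr$best)
      p <- file.path(out_dir, "search_summary.json")
      jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, p)
    }
  }

  # -- plan -------------------------------------------------------------
  if ("plan" %in% config$stages) {
    res$plan <- plan_table(res$reports, res$m_per_regime, pop$true_yield,
                           h2 = config$h2, R = config$reliability_target,
                           budget = config$budget)
    put(res$plan, "planning.csv")
  }

  # -- recommend --------------------------------------------------------
  if ("recommend" %in% config$stages) {
    qual <- filter_qualifying(lapply(seq_len(nrow(res$search$trace)),
                                     function(i) as.integer(strsplit(
                                       res$search$trace$days[i], ";")[[1]])),
                              res$search$trace$top_overlap,
                              threshold = config$qualify_threshold)
    res$qualifying_fraction <- qual$fraction
    if (length(qual$tdsrs) >= 10) {
      ws <- position_distributions(qual$tdsrs, config$m)
      ks <- ks_uniformity_test(ws, L = config$L)
      res$windows <- cbind(ws$positions, ks[, c("ks_stat", "p_value")])
      put(res$windows, "windows.csv")
    } else {
      res$windows <- NULL
      message("fewer than 10 qualifying regimes; no window recommendation")
    }
  }

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    package = "tdregimes",
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "vc")]),
    varcomps = list(G = unname(config$vc$G), E_diag = unname(diag(config$vc$E)),
                    sigma_eps2 = config$vc$sigma_eps2),
    artifacts = data.frame(file = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
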