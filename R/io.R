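#' Read a pedigree CSV
#'
#' Headered CSV with columns `animal,sire,dam`, one row per animal, parents
#' before offspring. Unknown parents may be blank or `"0"`.
#'
#' @param path file path.
#' @return a [pedigree()].
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  }
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree CSV
#' @param ped a [pedigree()].
#' @param path file path.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read test-day records from CSV
#'
#' Headered CSV with columns `cow,dim,yield`. Rows with non-numeric or
#' out-of-range entries (`dim` outside `[1, L]`, missing yield) are
#' rejected; their row numbers are reported in a warning and in the
#' `rejected_rows` attribute.
#'
#' @param path file path.
#' @param L lactation length bounding valid `dim`.
#' @return data.frame `cow`, `dim`, `yield` with attribute
#'   `rejected_rows`.
#' @export
read_testday_csv <- function(path, L = 280) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow", "dim", "yield")
  if (!all(need %in% names(df))) {
    stop("test-day file must have columns: ", paste(need, collapse = ", "))
  }
  dim_n <- suppressWarnings(as.numeric(df$dim))
  yld_n <- suppressWarnings(as.numeric(df$yield))
  bad <- is.na(dim_n) | is.na(yld_n) | dim_n < 1 | dim_n > L |
    dim_n != round(dim_n)
  if (any(bad)) {
    warning("rejected ", sum(bad), " test-day row(s): ",
            paste(utils::head(which(bad), 10), collapse = ", "))
  }
  out <- data.frame(cow = as.character(df$cow)[!bad], dim = as.integer(dim_n[!bad]),
                    yield = yld_n[!bad], stringsAsFactors = FALSE)
  attr(out, "rejected_rows") <- which(bad)
  attr(out, "L") <- L
  out
}

#' Write test-day records to CSV
#' @param records data.frame `cow`, `dim`, `yield`.
#' @param path file path.
#' @export
write_testday_csv <- function(records, path) {
  utils::write.csv(records[, c("cow", "dim", "yield")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with explicit keys for the scenario, pedigree shape,
#' variance components (`G` as its 6 free entries, diagonal `E`,
#' `sigma_eps2`), lactation length and seed. Missing keys fall back to the
#' package defaults; see `run_config()` for the field list. An annotated
#' default ships at `system.file("extdata", "default_config.yaml",
#' package = "tdregimes")`.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vc <- NULL
  if (!is.null(raw$varcomps)) {
    v <- raw$varcomps
    G <- matrix(0, 3, 3)
    G[upper.tri(G, diag = TRUE)] <- as.numeric(v$G)
    G <- G + t(G) - diag(diag(G))
    vc <- variance_components(G, diag(as.numeric(v$E_diag)),
                              as.numeric(v$sigma_eps2))
  }
  do.call(run_config, c(
    list(scenario = raw$scenario %||% "APHP",
         n_sires = raw$n_sires %||% 82,
         n_dams = raw$n_dams %||% 464,
         L = raw$lactation_length %||% 280,
         seed = raw$seed %||% 1,
         vc = vc),
    raw[intersect(names(raw),
                  c("schedules", "m", "loops", "coverage", "h2", "top_k",
                    "reliability_target", "budget", "stages",
                    "qualify_threshold"))]))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param scenario `"APHP"` or `"HPLP"`.
#' @param n_sires,n_dams synthetic pedigree shape (defaults 82 sires, 464
#'   cows, the study herd structure).
#' @param L lactation length (default 280 days).
#' @param vc variance components (default [default_varcomps()]).
#' @param schedules equally spaced schedules to evaluate.
#' @param m days per regime in the search.
#' @param loops,coverage search settings.
#' @param h2 heritability used in BLUP and planning.
#' @param top_k Top-k size for ranking agreement.
#' @param qualify_threshold overlap needed to qualify a regime.
#' @param reliability_target target sire reliability for planning.
#' @param budget total test-day records for planning.
#' @param seed master seed (substreams are derived per stage).
#' @param stages subset of `c("simulate", "estimate", "ebv", "search",
#'   "plan", "recommend")`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(scenario = "APHP", n_sires = 82, n_dams = 464,
                       L = 280, vc = NULL,
                       schedules = c("weekly", "monthly", "quarterly"),
                       m = 4, loops = 10, coverage = 25, h2 = 0.2,
                       top_k = 100, qualify_threshold = 80,
                       reliability_target = 0.5, budget = 7500, seed = 1,
                       stages = c("simulate", "estimate", "ebv", "search",
                                  "plan", "recommend")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!scenario %in% c("APHP", "HPLP")) stop("unknown scenario: ", scenario)
  if (m > L) stop("'m' cannot exceed the pool of DIM")
  if (top_k > n_dams) stop("'top_k' cannot exceed the number of cows")
  if (qualify_threshold > top_k) stop("'qualify_threshold' cannot exceed 'top_k'")
  if (reliability_target <= 0 || reliability_target >= 1) {
    stop("'reliability_target' must be in (0, 1)")
  }
  structure(list(scenario = scenario, n_sires = n_sires, n_dams = n_dams,
                 L = L, vc = vc %||% default_varcomps(),
                 schedules = schedules, m = m, loops = loops,
                 coverage = coverage, h2 = h2, top_k = top_k,
                 qualify_threshold = qualify_threshold,
                 reliability_target = reliability_target, budget = budget,
                 seed = seed, stages = stages),
            class = "run_config")
}
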