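#' Construct a growth-medium specification
#'
#' A medium overrides exchange-reaction bounds (in mmol gDW^-1 h^-1) and
#' declares which exchanges are carbon sources, so a carbon screen can
#' close them all and open one at a time.
#'
#' @param bounds Named list or two-column matrix: exchange reaction id ->
#'   `c(lower_bound, upper_bound)`.
#' @param carbon_exchange_ids Character vector, subset of `names(bounds)`
#'   (ids absent from `bounds` are allowed only if present in the model).
#' @return A list of class `medium_spec`.
#' @export
medium_spec <- function(bounds = list(), carbon_exchange_ids = character()) {
  bounds <- lapply(bounds, as.numeric)
  for (id in names(bounds)) {
    if (length(bounds[[id]]) != 2L || bounds[[id]][1] > bounds[[id]][2])
      pm_config_error("medium bound for '%s' must be c(lower, upper) with lower <= upper", id)
  }
  structure(list(bounds = bounds,
                 carbon_exchange_ids = as.character(carbon_exchange_ids)),
            class = "medium_spec")
}

#' Read a medium specification from YAML
#'
#' Expected structure: `bounds: {EX_x: [lo, hi], ...}` and
#' `carbon_exchange_ids: [...]`.
#'
#' @param path YAML path.
#' @return A [medium_spec].
#' @export
read_medium_yaml <- function(path) {
  if (!file.exists(path)) pm_data_error("medium YAML not found: %s", path)
  y <- yaml::read_yaml(path)
  medium_spec(bounds = y$bounds %||% list(),
              carbon_exchange_ids = unlist(y$carbon_exchange_ids) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Build the stoichiometric matrix (metabolites x reactions).
stoich_matrix <- function(m) {
  rids <- names(m$reactions)
  mids <- m$metabolites$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in m$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction flux subject to steady state
#' (`S v = 0`) and flux bounds, with model bounds overridden by the medium
#' for the listed exchanges. Solved as a linear program (simplex, via
#' pracma) on shifted non-negative variables, which keeps the formulation
#' solver-friendly for bounded problems; infinite bounds are capped at
#' `default_bound`. The objective value is the contract of this function:
#' individual fluxes are generally not unique under degeneracy.
#'
#' @param m A `metabolic_model`.
#' @param medium Optional [medium_spec].
#' @param default_bound Cap for infinite bounds (default 1000).
#' @return A list of class `flux_solution` with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, `fluxes` (named
#'   numeric) and `residual` (max abs steady-state violation).
#' @export
solve_fba <- function(m, medium = NULL, default_bound = 1000) {
  validate_model(m)
  rids <- names(m$reactions)
  lb <- vapply(m$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(m$reactions, `[[`, numeric(1), "upper_bound")
  if (!is.null(medium)) {
    unknown <- setdiff(names(medium$bounds), rids)
    if (length(unknown))
      pm_data_error("medium references unknown exchange(s): %s",
                    paste(unknown, collapse = ", "))
    for (id in names(medium$bounds)) {
      lb[id] <- medium$bounds[[id]][1]; ub[id] <- medium$bounds[[id]][2]
    }
  }
  lb <- pmax(lb, -default_bound); ub <- pmin(ub, default_bound)
  S <- stoich_matrix(m)
  obj <- as.numeric(rids == m$objective)
  n <- length(rids)
  ## shift to non-negative variables: v = x + lb, x in [0, ub - lb]
  rng <- ub - lb
  beq <- as.vector(-S %*% lb)
  sol <- tryCatch(
    pracma::linprog(cc = obj, A = diag(n), b = rng, Aeq = S, beq = beq,
                    maximize = TRUE, maxiter = max(200L, 20L * n)),
    error = function(e) NULL)
  empty_status <- function(status) {
    structure(list(status = status, objective_value = NA_real_,
                   fluxes = stats::setNames(rep(NA_real_, n), rids),
                   residual = NA_real_), class = "flux_solution")
  }
  if (is.null(sol) || is.null(sol$x) || anyNA(sol$x)) {
    if (!is.null(sol$errno) && sol$errno == -1)
      pm_data_error("LP iteration limit reached; model too large for the simplex settings")
    return(empty_status(if (!is.null(sol$errno) && sol$errno == -3)
      "unbounded" else "infeasible"))
  }
  v <- sol$x + lb
  names(v) <- rids
  residual <- if (nrow(S)) max(abs(S %*% v)) else 0
  structure(list(status = "optimal",
                 objective_value = unname(v[m$objective]),
                 fluxes = v, residual = residual),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: %s, objective %.6g\n", x$status, x$objective_value))
  invisible(x)
}

#' Carbon-source growth screen
#'
#' For each panel source, starts from the base medium with every declared
#' carbon exchange closed to uptake (lower bound 0), opens only the current
#' source at `-uptake_rate`, and solves the FBA problem. A source supports
#' growth iff the optimal objective exceeds `growth_epsilon`. Panel ids
#' absent from the model are reported with `absent = TRUE` and no growth.
#' Results are independent of panel order.
#'
#' @param m A `metabolic_model`.
#' @param base_medium A [medium_spec]; its `carbon_exchange_ids` (plus the
#'   panel) define which exchanges are closed between tests.
#' @param panel Ordered character vector of exchange reaction ids to test.
#' @param uptake_rate Uptake bound magnitude per opened source (default 10
#'   mmol gDW^-1 h^-1).
#' @param growth_epsilon Objective threshold for calling growth
#'   (default 1e-6).
#' @return A list of class `carbon_screen` with `results` (data frame:
#'   `source`, `objective`, `grows`, `absent`, `status`), `n_tested`,
#'   `n_growth`, `growth_epsilon`.
#' @export
carbon_source_screen <- function(m, base_medium = medium_spec(), panel,
                                 uptake_rate = 10, growth_epsilon = 1e-6) {
  pm_assert_scalar_number(uptake_rate, "uptake_rate", min = 0)
  pm_assert_scalar_number(growth_epsilon, "growth_epsilon", min = 0)
  validate_model(m)
  carbons <- union(base_medium$carbon_exchange_ids, panel)
  absent <- setdiff(panel, names(m$reactions))
  if (length(absent))
    message(sprintf("%d panel source(s) absent from the model: %s",
                    length(absent), paste(utils::head(absent, 5), collapse = ", ")))
  rows <- lapply(panel, function(src) {
    if (!src %in% names(m$reactions))
      return(data.frame(source = src, objective = NA_real_, grows = FALSE,
                        absent = TRUE, status = "absent", stringsAsFactors = FALSE))
    med <- base_medium
    for (cx in intersect(carbons, names(m$reactions))) {
      cur <- med$bounds[[cx]] %||%
        c(m$reactions[[cx]]$lower_bound, m$reactions[[cx]]$upper_bound)
      med$bounds[[cx]] <- c(0, max(0, cur[2]))
    }
    med$bounds[[src]][1] <- -uptake_rate
    sol <- solve_fba(m, med)
    data.frame(source = src,
               objective = if (sol$status == "optimal") sol$objective_value else 0,
               grows = sol$status == "optimal" && sol$objective_value > growth_epsilon,
               absent = FALSE, status = sol$status, stringsAsFactors = FALSE)
  })
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), objective = numeric(), grows = logical(),
               absent = logical(), status = character(), stringsAsFactors = FALSE)
  structure(list(results = results, n_tested = length(panel),
                 n_growth = sum(results$grows), growth_epsilon = growth_epsilon),
            class = "carbon_screen")
}

#' @export
print.carbon_screen <- function(x, ...) {
  cat(sprintf("carbon_screen: growth on %d of %d sources (epsilon %.1g)\n",
              x$n_growth, x$n_tested, x$growth_epsilon))
  invisible(x)
}

#' Write carbon-screen results to TSV
#'
#' @param screen A `carbon_screen`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
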