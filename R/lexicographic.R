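# Lexicographic (wish-list) multi-criteria optimization over spot weights.
#
# Every stage is a sparse LP in the non-negative spot weights w plus
# auxiliary variables: one deficit variable per target voxel for
# mean-underdose objectives (voxel-wise-minimum semantics across robust
# scenarios) and one bound variable t per max/mean objective (worst case
# across scenarios via d <= t rows). Hard constraints hold in every
# required scenario at every stage; optimized objectives are frozen at
# achieved x slack (or at their goal when flagged sufficient) before the
# next priority is minimized.

.as_mats <- function(influences) {
  lapply(influences, function(x) {
    if (methods::is(x, "InfluenceMatrix")) x@mat
    else methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  })
}

.parse_struct <- function(name, structures) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  idx <- integer(0)
  for (p in parts) {
    v <- structures[[p]]
    if (is.null(v)) .stopf("wish-list references unknown structure '%s'", p)
    idx <- c(idx, v)
  }
  sort(unique(idx))
}

.lex_init <- function(wishlist, influences, structures, spots = NULL,
                      nominal = NULL) {
  st <- new.env(parent = emptyenv())
  st$mats <- .as_mats(influences)
  if (is.null(names(st$mats)) || any(!nzchar(names(st$mats)))) {
    names(st$mats) <- sprintf("s%02d", seq_along(st$mats))
  }
  st$nominal <- if (is.null(nominal)) names(st$mats)[1] else nominal
  st$n_w <- ncol(st$mats[[1]])
  st$structures <- structures
  st$wl <- wishlist
  st$spot_beam <- if (!is.null(spots)) spots@spots$beam_index else NULL

  ob <- wishlist@objectives
  # variable layout: w | u-blocks | t-columns
  off <- st$n_w
  st$u_off <- vector("list", nrow(ob))
  st$t_col <- rep(NA_integer_, nrow(ob))
  for (k in seq_len(nrow(ob))) {
    if (ob$type[k] == "mean_underdose") {
      n_s <- length(.parse_struct(ob$structure[k], structures))
      st$u_off[[k]] <- c(off, n_s)
      off <- off + n_s
    } else {
      st$t_col[k] <- off + 1L
      off <- off + 1L
    }
  }
  st$n_var <- off
  st$ub <- rep(Inf, st$n_var)
  st$blocks_A <- list()
  st$blocks_b <- list()
  st$achieved <- rep(NA_real_, nrow(ob))
  st$log <- character()

  # hard constraints
  cn <- wishlist@constraints
  for (i in seq_len(nrow(cn))) {
    rows <- .parse_struct(cn$structure[i], structures)
    scen <- if (cn$robust[i]) names(st$mats) else st$nominal
    for (s in scen) {
      M <- st$mats[[s]]
      if (cn$metric[i] == "max_dose") {
        .add_dose_rows(st, M, rows, rhs = cn$bound[i])
      } else if (cn$metric[i] == "mean_dose") {
        .add_mean_row(st, M, rows, rhs = cn$bound[i])
      } else if (cn$metric[i] == "per_beam_max_dose") {
        if (is.null(st$spot_beam)) {
          .stopf("per_beam_max_dose constraint requires the spot catalog")
        }
        for (b in sort(unique(st$spot_beam))) {
          .add_dose_rows(st, M, rows, rhs = cn$bound[i],
                         col_keep = which(st$spot_beam == b))
        }
      }
    }
  }
  st
}

# append rows  M[rows, cols] w (+ t_coef * x_tcol) <= rhs
.add_dose_rows <- function(st, M, rows, rhs, col_keep = NULL, t_col = NULL,
                           u_off = NULL, negate = FALSE) {
  Msub <- M[rows, , drop = FALSE]
  T <- methods::as(methods::as(Msub, "generalMatrix"), "TsparseMatrix")
  i <- T@i + 1L; j <- T@j + 1L; x <- T@x
  if (!is.null(col_keep)) {
    keep <- j %in% col_keep
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  if (negate) x <- -x
  n <- length(rows)
  if (!is.null(t_col)) {
    i <- c(i, seq_len(n)); j <- c(j, rep(t_col, n)); x <- c(x, rep(-1, n))
  }
  if (!is.null(u_off)) {   # u_off = c(offset, n): -I on the u block
    i <- c(i, seq_len(n)); j <- c(j, u_off[1] + seq_len(n)); x <- c(x, rep(-1, n))
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, st$n_var))
  st$blocks_A[[length(st$blocks_A) + 1L]] <- A
  st$blocks_b[[length(st$blocks_b) + 1L]] <- rep(rhs, length.out = n)
  invisible(NULL)
}

.add_mean_row <- function(st, M, rows, rhs, t_col = NULL) {
  cm <- Matrix::colSums(M[rows, , drop = FALSE]) / length(rows)
  j <- which(cm != 0); x <- cm[j]
  if (!is.null(t_col)) { j <- c(j, t_col); x <- c(x, -1) }
  A <- Matrix::sparseMatrix(i = rep(1L, length(j)), j = j, x = x,
                            dims = c(1L, st$n_var))
  st$blocks_A[[length(st$blocks_A) + 1L]] <- A
  st$blocks_b[[length(st$blocks_b) + 1L]] <- rhs
  invisible(NULL)
}

.add_generic_row <- function(st, j, x, rhs) {
  A <- Matrix::sparseMatrix(i = rep(1L, length(j)), j = j, x = x,
                            dims = c(1L, st$n_var))
  st$blocks_A[[length(st$blocks_A) + 1L]] <- A
  st$blocks_b[[length(st$blocks_b) + 1L]] <- rhs
  invisible(NULL)
}

.lex_solve_lp <- function(st, obj, stage_label) {
  # incremental assembly: only blocks added since the last solve are bound
  nb <- length(st$blocks_A)
  if (nb == 0L) {
    res <- solveLP(obj, NULL, numeric(0), lb = 0, ub = st$ub)
    st$log <- c(st$log, sprintf("%s: objective %.8g (unconstrained)",
                                stage_label, res$objective))
    return(res)
  }
  if (is.null(st$A_cache)) {
    st$A_cache <- do.call(rbind, st$blocks_A)
    st$n_cached <- nb
  } else if (nb > st$n_cached) {
    st$A_cache <- do.call(rbind, c(list(st$A_cache),
                                   st$blocks_A[(st$n_cached + 1L):nb]))
    st$n_cached <- nb
  }
  A <- st$A_cache
  b <- unlist(st$blocks_b, use.names = FALSE)
  t0 <- Sys.time()
  res <- solveLP(obj, A, b, lb = 0, ub = st$ub, allow_infeasible = TRUE)
  if (res$status != 0) {
    .stopf("stage '%s' infeasible or unsolved (status %d): %s",
           stage_label, res$status, res$message)
  }
  st$log <- c(st$log, sprintf("%s: objective %.8g, %d rows, %d nnz, %.1fs",
                              stage_label, res$objective, nrow(A),
                              length(A@x),
                              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# run stages `ks` (indices into the objective table) assuming earlier ones
# are already frozen in the state; returns last solution x.
# freeze_override[k], when finite, replaces the stage-k freeze bound
# (used to re-solve under externally fixed stage budgets).
.lex_run <- function(st, ks = NULL, freeze_override = NULL) {
  ob <- st$wl@objectives
  if (is.null(ks)) ks <- seq_len(nrow(ob))
  slack <- st$wl@slack
  x <- NULL
  if (!nrow(ob)) {  # feasibility-only problem
    res <- .lex_solve_lp(st, numeric(st$n_var), "feasibility")
    return(res$x)
  }
  for (k in ks) {
    rows <- .parse_struct(ob$structure[k], st$structures)
    scen <- if (ob$robust[k]) names(st$mats) else st$nominal
    obj <- numeric(st$n_var)
    if (ob$type[k] == "mean_underdose") {
      uo <- st$u_off[[k]]
      for (s in scen) {
        .add_dose_rows(st, st$mats[[s]], rows, rhs = -ob$goal[k],
                       u_off = uo, negate = TRUE)
      }
      obj[uo[1] + seq_len(uo[2])] <- 1 / uo[2]
    } else {
      tc <- st$t_col[k]
      for (s in scen) {
        if (ob$type[k] == "max_dose") {
          .add_dose_rows(st, st$mats[[s]], rows, rhs = 0, t_col = tc)
        } else {
          .add_mean_row(st, st$mats[[s]], rows, rhs = 0, t_col = tc)
        }
      }
      obj[tc] <- 1
    }
    lab <- sprintf("P%d %s %s", ob$priority[k], ob$structure[k], ob$type[k])
    res <- .lex_solve_lp(st, obj, lab)
    ach <- res$objective
    st$achieved[k] <- ach
    x <- res$x
    # freeze
    bound <- max(ach * slack, ach + 1e-4)
    if (isTRUE(ob$sufficient[k])) {
      goal_obj <- if (ob$type[k] == "mean_underdose") 0 else ob$goal[k]
      bound <- max(bound, goal_obj)
    }
    if (!is.null(freeze_override) && is.finite(freeze_override[k])) {
      bound <- freeze_override[k]
    }
    if (ob$type[k] == "mean_underdose") {
      uo <- st$u_off[[k]]
      .add_generic_row(st, j = uo[1] + seq_len(uo[2]),
                       x = rep(1 / uo[2], uo[2]), rhs = bound)
    } else {
      st$ub[st$t_col[k]] <- bound
    }
    st$frozen_bounds <- c(st$frozen_bounds, stats::setNames(bound, lab))
  }
  x
}

.dummy_spots <- function(n) {
  new("SpotSet",
      spots = data.frame(spot_id = seq_len(n), beam_index = 1L,
                         gantry_angle = 0, u = seq_len(n), v = 0,
                         energy = 100, shifter_wet_cm = 0,
                         is_transmission = FALSE, target = "none",
                         stringsAsFactors = FALSE),
      isocenter = c(0, 0, 0), meta = list())
}

#' Lexicographic wish-list optimization of spot weights
#'
#' Minimizes the wish-list objectives in priority order: each stage is a
#' sparse LP subject to (i) all hard constraints in every required
#' scenario, (ii) every earlier objective frozen at achieved x slack (or
#' at its goal when sufficient), (iii) the per-beam dose cap, (iv)
#' non-negative weights. Robust objectives are scored worst-case over the
#' supplied scenarios (voxel-wise minimum for underdose). A stage that
#' cannot be solved raises an error naming the stage; hard constraints are
#' never silently relaxed.
#'
#' @param wishlist a [WishList-class].
#' @param influences named list of [InfluenceMatrix-class] (or bare
#'   matrices) over the optimization scenarios; the nominal scenario must
#'   be the first element (or named via `nominal`).
#' @param structures named list: structure name -> integer row indices
#'   into the influence matrices. When influences are InfluenceMatrix
#'   objects built from a phantom, use [structureRows()].
#' @param spots the candidate [SpotSet-class] (required for per-beam
#'   constraints; optional for toy problems).
#' @param nominal name of the nominal scenario.
#' @param freeze_bounds optional numeric vector (one entry per objective):
#'   a finite value replaces the achieved-times-slack freeze bound of that
#'   stage, so later stages are optimized under externally fixed budgets
#'   for the earlier objectives (useful for controlled candidate-set
#'   comparisons and epsilon-constraint studies).
#' @return a [PlanSolution-class] (weights, achieved objective values,
#'   active spots at the 1e-9 level, solver log).
#' @export
solveLexicographic <- function(wishlist, influences, structures,
                               spots = NULL, nominal = NULL,
                               freeze_bounds = NULL) {
  st <- .lex_init(wishlist, influences, structures, spots, nominal)
  x <- .lex_run(st, freeze_override = freeze_bounds)
  w <- x[seq_len(st$n_w)]
  w[w < 0] <- 0
  ob <- wishlist@objectives
  ach <- data.frame(priority = ob$priority, structure = ob$structure,
                    type = ob$type, value = st$achieved,
                    stringsAsFactors = FALSE)
  sp <- if (is.null(spots)) .dummy_spots(st$n_w) else spots
  tb <- sp@spots$is_transmission
  act <- which(w > 1e-9)
  new("PlanSolution", weights = w, spots = sp, achieved = ach,
      active = act,
      tb_fraction = if (any(tb)) sum(tb[act]) / max(1L, length(act)) else NA_real_,
      log = st$log,
      meta = list(frozen_bounds = st$frozen_bounds,
                  scenario_names = names(st$mats),
                  wishlist = wishlist@meta$name))
}

#' Sparsity-induced spot selection (SISS)
#'
#' Appends a sparsity stage to a solved lexicographic plan: with every
#' wish-list objective frozen, an iteratively reweighted L1 norm of the
#' spot weights is minimized (weights 1/(w + eps), deterministic
#' smallest-index tie-break), spots below the prune threshold are removed,
#' and the full lexicographic problem is re-solved on the surviving
#' candidates. If the re-solve fails, the pruned spots are restored and
#' the dense solution returned (reported in the log).
#'
#' @param solution a [PlanSolution-class] from [solveLexicographic()].
#' @param influences,structures,spots,nominal as in [solveLexicographic()].
#' @param wishlist the same [WishList-class] used for `solution`.
#' @param sparsity a [sissConfig()]; with `n_reweight = 0` and
#'   `prune_rel = 0` the solution is returned unchanged.
#' @return a [PlanSolution-class] with the pruned candidate support; the
#'   transmission-spot fraction of the active set is reported in
#'   `tbFraction()`.
#' @export
sissSelect <- function(solution, influences, wishlist, structures,
                       spots = NULL, nominal = NULL,
                       sparsity = sissConfig()) {
  if (sparsity$n_reweight == 0 && sparsity$prune_rel == 0) return(solution)
  st <- .lex_init(wishlist, influences, structures, spots, nominal)
  .lex_run(st)   # rebuild and freeze all stages
  n_w <- st$n_w
  w <- solution@weights
  for (it in seq_len(sparsity$n_reweight)) {
    eps <- 1e-3 * max(w, 1e-12)
    r <- 1 / (w + eps)
    r <- r * (1 + 1e-9 * seq_len(n_w))   # deterministic tie-break: keep low index
    obj <- numeric(st$n_var)
    obj[seq_len(n_w)] <- r / max(r)
    res <- .lex_solve_lp(st, obj, sprintf("siss reweight %d", it))
    w <- res$x[seq_len(n_w)]
    w[w < 0] <- 0
  }
  thr <- sparsity$prune_rel * max(w, 0)
  keep <- which(w > thr)
  lab <- sprintf("siss: pruned %d of %d candidates", n_w - length(keep), n_w)
  sub_infl <- lapply(.as_mats(influences), function(M) M[, keep, drop = FALSE])
  sub_spots <- if (!is.null(spots)) subsetSpots(spots, keep) else NULL
  refit <- tryCatch(
    solveLexicographic(wishlist, sub_infl, structures, sub_spots, nominal),
    error = function(e) e)
  if (inherits(refit, "error")) {
    solution@log <- c(solution@log, st$log, lab,
                      paste("siss: re-solve failed, pruned spots restored:",
                            conditionMessage(refit)))
    return(solution)
  }
  w_full <- numeric(n_w)
  w_full[keep] <- refit@weights
  sp <- if (is.null(spots)) .dummy_spots(n_w) else spots
  tb <- sp@spots$is_transmission
  act <- keep[refit@weights > 1e-9]
  new("PlanSolution", weights = w_full, spots = sp,
      achieved = refit@achieved, active = act,
      tb_fraction = if (any(tb)) sum(tb[act]) / max(1L, length(act)) else NA_real_,
      log = c(solution@log, st$log, lab, refit@log),
      meta = c(refit@meta, list(siss = unclass(sparsity),
                                dense_achieved = solution@achieved,
                                dense_frozen = solution@meta$frozen_bounds)))
}

#' SISS configuration
#'
#' @param n_reweight iterations of the reweighted L1 minimization
#'   (default 2).
#' @param prune_rel prune threshold relative to the maximum spot weight
#'   (default 1e-3).
#' @return list of class "siss_config"
#' @export
sissConfig <- function(n_reweight = 2L, prune_rel = 1e-3) {
  if (n_reweight < 0 || prune_rel < 0) .stopf("siss parameters must be >= 0")
  structure(list(n_reweight = as.integer(n_reweight), prune_rel = prune_rel),
            class = "siss_config")
}

#' Map phantom structures to influence-matrix rows
#'
#' @param phantom a [VoxelPhantom-class].
#' @param influence an [InfluenceMatrix-class] built from the phantom (its
#'   rows index the body voxels).
#' @param names structure names (default: all, plus "body").
#' @return named list of integer row indices.
#' @export
structureRows <- function(phantom, influence, names = NULL) {
  if (is.null(names)) names <- c(structureNames(phantom), "body")
  lut <- integer(prod(phantom@grid))
  lut[influence@voxel_idx] <- seq_along(influence@voxel_idx)
  out <- lapply(names, function(nm) {
    rows <- lut[which(structureMask(phantom, nm))]
    rows[rows > 0L]
  })
  stats::setNames(out, names)
}

#' Verify wish-list hard constraints for given weights
#'
#' Recomputes every hard-constraint dose quantity from the influence
#' matrices and reports the worst residual (value - bound) per constraint
#' and scenario.
#'
#' @inheritParams solveLexicographic
#' @param weights numeric spot weights.
#' @return data.frame(structure, metric, scenario, bound, value, residual).
#' @export
checkConstraints <- function(wishlist, influences, structures, weights,
                             spots = NULL, nominal = NULL) {
  mats <- .as_mats(influences)
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    names(mats) <- sprintf("s%02d", seq_along(mats))
  }
  nom <- if (is.null(nominal)) names(mats)[1] else nominal
  cn <- wishlist@constraints
  out <- list()
  for (i in seq_len(nrow(cn))) {
    rows <- .parse_struct(cn$structure[i], structures)
    scen <- if (cn$robust[i]) names(mats) else nom
    for (s in scen) {
      d <- as.numeric(mats[[s]][rows, , drop = FALSE] %*% weights)
      val <- switch(cn$metric[i],
        max_dose = max(d),
        mean_dose = mean(d),
        per_beam_max_dose = {
          if (is.null(spots)) .stopf("per-beam check requires the spot catalog")
          mx <- 0
          for (b in unique(spots@spots$beam_index)) {
            wb <- weights
            wb[spots@spots$beam_index != b] <- 0
            mx <- max(mx, max(as.numeric(mats[[s]][rows, , drop = FALSE] %*% wb)))
          }
          mx
        })
      out[[length(out) + 1L]] <- data.frame(
        structure = cn$structure[i], metric = cn$metric[i], scenario = s,
        bound = cn$bound[i], value = val, residual = val - cn$bound[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @rdname accessors
#' @export
setMethod("spotWeights", "PlanSolution", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("achievedValues", "PlanSolution", function(x) x@achieved)

#' @rdname accessors
#' @export
setMethod("activeSpots", "PlanSolution", function(x) x@active)

#' @rdname accessors
#' @export
setMethod("tbFraction", "PlanSolution", function(x) x@tb_fraction)
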