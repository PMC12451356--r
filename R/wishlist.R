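#' Construct a wish-list
#'
#' A wish-list is the planning protocol of the lexicographic optimizer:
#' hard constraints that may never be violated, and prioritized objectives
#' that are minimized one after the other, each previous objective being
#' frozen at its achieved value times a small slack before the next is
#' optimized.
#'
#' @param constraints data.frame(structure, metric, bound, robust);
#'   metrics: "max_dose" (Gy upper bound per voxel), "mean_dose" (Gy upper
#'   bound on the structure mean), "per_beam_max_dose" (Gy upper bound on
#'   any voxel's dose from a single beam).
#' @param objectives data.frame(priority, structure, type, goal, robust,
#'   sufficient); types: "max_dose", "mean_dose", "mean_underdose" (mean
#'   one-sided deficit below `goal`, the linear target-coverage surrogate).
#'   `structure` may join several structures with "+" (union).
#'   Robust max/mean items are scored worst-case over the optimization
#'   scenarios; robust underdose uses voxel-wise-minimum semantics. With
#'   `sufficient = TRUE` an objective that reaches its goal is frozen at
#'   the goal rather than at the (better) achieved value, leaving room for
#'   lower priorities.
#' @param slack multiplicative freeze slack, default 1.03.
#' @param name label stored in the meta slot.
#' @return a [WishList-class]
#' @export
wishList <- function(constraints = NULL, objectives = NULL, slack = 1.03,
                     name = "custom") {
  empty_c <- data.frame(structure = character(), metric = character(),
                        bound = numeric(), robust = logical(),
                        stringsAsFactors = FALSE)
  empty_o <- data.frame(priority = integer(), structure = character(),
                        type = character(), goal = numeric(),
                        robust = logical(), sufficient = logical(),
                        stringsAsFactors = FALSE)
  cn <- if (is.null(constraints) || !nrow(constraints)) empty_c else constraints
  ob <- if (is.null(objectives) || !nrow(objectives)) empty_o else
    objectives[order(objectives$priority), , drop = FALSE]
  rownames(cn) <- NULL; rownames(ob) <- NULL
  new("WishList", constraints = cn, objectives = ob, slack = slack,
      meta = list(name = name))
}

#' Default nasopharynx wish-list
#'
#' A prioritization in line with international head-and-neck practice:
#' hard serial-organ constraints first (brainstem and spinal cord core and
#' surface, optic chiasm and nerves, a global hot-spot cap and the
#' per-beam dose cap), then robust primary/elective target coverage,
#' nominal coverage fine-tuning, hot-spot control, serial-organ dose
#' minimization, parallel-organ mean doses and finally the integral dose
#' bath. This list is a configurable stand-in written for the synthetic
#' phantom, not a verbatim clinical protocol.
#'
#' @param presc a [prescriptionConfig()].
#' @param beams a [beamConfig()] (per-beam cap bound).
#' @return a [WishList-class]
#' @export
npcWishList <- function(presc = prescriptionConfig(), beams = beamConfig()) {
  th <- goalThresholds(presc)
  constraints <- data.frame(
    structure = c("brainstem", "brainstem_surface", "spinal_cord",
                  "spinal_cord_surface", "chiasm", "optic_nerve_l",
                  "optic_nerve_r", "ctv_ring", "ctv_ring"),
    metric = c(rep("max_dose", 8), "per_beam_max_dose"),
    bound = c(54, 60, 45, 50, 55, 55, 55, 1.10 * presc$d_high,
              beams$per_beam_dose_cap),
    robust = c(rep(TRUE, 7), FALSE, FALSE),
    stringsAsFactors = FALSE)
  objectives <- data.frame(
    priority = 1:8,
    structure = c("ctv7000_opt", "ctv5425_opt", "ctv_ring",
                  "brainstem+brainstem_surface",
                  "chiasm+optic_nerve_l+optic_nerve_r",
                  "parotid_l+parotid_r", "oral_cavity+pcm_superior",
                  "body_minus_ctvs"),
    type = c("mean_underdose", "mean_underdose", "max_dose", "max_dose",
             "max_dose", "mean_dose", "mean_dose", "mean_dose"),
    goal = c(th$ctv7000["d98_vwmin"], th$ctv5425["d98_vwmin"],
             th$ctv7000["d2"], 0, 0, 0, 0, 0),
    robust = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    sufficient = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  wishList(constraints, objectives, slack = 1.03, name = "npc_default")
}

#' Read / write a wish-list as YAML
#'
#' @param path YAML file.
#' @return [readWishList()]: a [WishList-class].
#' @export
readWishList <- function(path) {
  y <- yaml::read_yaml(path)
  cn <- if (length(y$constraints)) do.call(rbind, lapply(y$constraints, function(r) {
    data.frame(structure = r$structure, metric = r$metric, bound = r$bound,
               robust = isTRUE(r$robust), stringsAsFactors = FALSE)
  })) else NULL
  ob <- if (length(y$objectives)) do.call(rbind, lapply(y$objectives, function(r) {
    data.frame(priority = r$priority, structure = r$structure, type = r$type,
               goal = if (is.null(r$goal)) 0 else r$goal,
               robust = isTRUE(r$robust), sufficient = isTRUE(r$sufficient),
               stringsAsFactors = FALSE)
  })) else NULL
  wishList(cn, ob, slack = if (is.null(y$slack)) 1.03 else y$slack,
           name = if (is.null(y$name)) basename(path) else y$name)
}

#' @rdname readWishList
#' @param wl a [WishList-class]
#' @export
writeWishList <- function(wl, path) {
  y <- list(
    name = wl@meta$name, slack = wl@slack,
    constraints = lapply(seq_len(nrow(wl@constraints)), function(i) {
      as.list(wl@constraints[i, ])
    }),
    objectives = lapply(seq_len(nrow(wl@objectives)), function(i) {
      as.list(wl@objectives[i, ])
    }))
  yaml::write_yaml(y, path)
  invisible(path)
}
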