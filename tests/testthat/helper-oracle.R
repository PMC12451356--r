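# Independent lexicographic oracle: dense epsilon-constraint formulation
# solved with pracma's simplex (a different solver and a separate
# assembly path from the package implementation).

# exact two-sided signed-rank p by full sign enumeration
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Primary oracle solver: pracma's dense simplex (entirely independent of
# the package backend). Its textbook pivoting can hit singular bases on
# the degenerate stage structure; those instances fall back to HiGHS dual
# simplex (a different algorithm from the package's interior-point path)
# on the independently assembled dense model.
oracle_lp <- function(cc, A, b) {
  r <- tryCatch(pracma::linprog(cc, A = A, b = b, maxiter = 5000),
                error = function(e) NULL)
  if (!is.null(r) && r$errno == 1) return(r)
  old <- options(protonMCO.lp_method = "highs-ds")
  on.exit(options(old), add = TRUE)
  s <- solveLP(cc, A, b)
  list(x = s$x, fval = s$objective, errno = 1)
}

# returns the stage-wise achieved objective values
oracle_lexicographic <- function(wishlist, influences, structures) {
  mats <- lapply(influences, as.matrix)
  nominal <- 1L
  ob <- wishlist@objectives
  cn <- wishlist@constraints
  n_w <- ncol(mats[[1]])
  slack <- wishlist@slack
  eps <- rep(NA_real_, nrow(ob))
  achieved <- rep(NA_real_, nrow(ob))

  rows_of <- function(nm) {
    idx <- integer(0)
    for (p in strsplit(nm, "+", fixed = TRUE)[[1]]) idx <- c(idx, structures[[p]])
    sort(unique(idx))
  }

  for (k in seq_len(nrow(ob))) {
    # variable layout for this stage: w | u_1..u_k (underdose only) | t
    u_off <- list(); off <- n_w
    for (j in seq_len(k)) {
      if (ob$type[j] == "mean_underdose") {
        nS <- length(rows_of(ob$structure[j]))
        u_off[[j]] <- c(off, nS); off <- off + nS
      }
    }
    has_t <- ob$type[k] != "mean_underdose"
    t_col <- if (has_t) off + 1L else NA_integer_
    n_var <- off + as.integer(has_t)

    A <- matrix(0, 0, n_var); b <- numeric(0)
    add <- function(Ar, br) { A <<- rbind(A, Ar); b <<- c(b, br) }

    for (i in seq_len(nrow(cn))) {
      rows <- rows_of(cn$structure[i])
      scen <- if (cn$robust[i]) seq_along(mats) else nominal
      for (s in scen) {
        Ms <- mats[[s]][rows, , drop = FALSE]
        if (cn$metric[i] == "max_dose") {
          Ar <- cbind(Ms, matrix(0, nrow(Ms), n_var - n_w))
          add(Ar, rep(cn$bound[i], nrow(Ms)))
        } else if (cn$metric[i] == "mean_dose") {
          Ar <- c(colMeans(Ms), numeric(n_var - n_w))
          add(matrix(Ar, 1), cn$bound[i])
        } else stop("oracle does not model per-beam constraints")
      }
    }

    for (j in seq_len(k)) {
      rows <- rows_of(ob$structure[j])
      scen <- if (ob$robust[j]) seq_along(mats) else nominal
      if (ob$type[j] == "mean_underdose") {
        uo <- u_off[[j]]; nS <- uo[2]
        for (s in scen) {
          Ar <- matrix(0, nS, n_var)
          Ar[, seq_len(n_w)] <- -mats[[s]][rows, , drop = FALSE]
          Ar[cbind(seq_len(nS), uo[1] + seq_len(nS))] <- -1
          add(Ar, rep(-ob$goal[j], nS))
        }
        if (j < k) {
          Ar <- numeric(n_var); Ar[uo[1] + seq_len(nS)] <- 1 / nS
          add(matrix(Ar, 1), eps[j])
        }
      } else {
        for (s in scen) {
          Ms <- mats[[s]][rows, , drop = FALSE]
          if (ob$type[j] == "mean_dose") Ms <- matrix(colMeans(Ms), 1)
          if (j < k) {
            add(cbind(Ms, matrix(0, nrow(Ms), n_var - n_w)), rep(eps[j], nrow(Ms)))
          } else {
            Ar <- cbind(Ms, matrix(0, nrow(Ms), n_var - n_w))
            Ar[, t_col] <- -1
            add(Ar, rep(0, nrow(Ms)))
          }
        }
      }
    }

    cc <- numeric(n_var)
    if (ob$type[k] == "mean_underdose") {
      uo <- u_off[[k]]
      cc[uo[1] + seq_len(uo[2])] <- 1 / uo[2]
    } else cc[t_col] <- 1
    r <- oracle_lp(cc, A, b)
    achieved[k] <- sum(cc * r$x)
    bound <- max(achieved[k] * slack, achieved[k] + 1e-4)
    if (isTRUE(ob$sufficient[k])) {
      goal_obj <- if (ob$type[k] == "mean_underdose") 0 else ob$goal[k]
      bound <- max(bound, goal_obj)
    }
    eps[k] <- bound
  }
  achieved
}
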