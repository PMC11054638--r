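# Shared fixtures and independent oracles for the test suite.

make_geom <- function() default_geometry()

make_series <- function(baso = c(100, 100, 100, 100), stock = 1000,
                        role = "cells", compound = "ibuprofen",
                        inhibitor = "none", channel = "mAU_min",
                        well_id = "w1") {
  well_series(well_id, role, compound, inhibitor = inhibitor,
              channel = channel, baso_signal = baso, stock_signal = stock)
}

# Independent closed-form receiver concentration for one interval of the
# two-compartment model with fresh receiver (Cb0 = 0), used as oracle.
oracle_interval_cb <- function(Ca0, ps, va, vb, dt) {
  k <- ps * (va + vb) / (va * vb)
  ceq <- Ca0 * va / (va + vb)
  ceq * (1 - exp(-k * dt))
}

# Brute-force Holm-Sidak step-down: walk the sorted p-values, apply the
# Sidak single-step factor for the remaining hypotheses, carry the running
# maximum. Written independently of the package implementation.
oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    step <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, step)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Hand-computed one-way ANOVA sums of squares.
oracle_oneway_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  lv <- unique(groups)
  ss_between <- sum(vapply(lv, function(g) {
    v <- values[groups == g]
    length(v) * (mean(v) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(lv, function(g) {
    v <- values[groups == g]
    sum((v - mean(v))^2)
  }, numeric(1)))
  df_b <- length(lv) - 1
  df_w <- length(values) - length(lv)
  (ss_between / df_b) / (ss_within / df_w)
}

# Hand-computed balanced two-way ANOVA F statistics (factors a, b).
oracle_twoway_F <- function(values, a, b) {
  a <- as.character(a); b <- as.character(b)
  grand <- mean(values)
  n_cell <- length(values) / (length(unique(a)) * length(unique(b)))
  ss_a <- sum(vapply(unique(a), function(x)
    sum(a == x) * (mean(values[a == x]) - grand)^2, numeric(1)))
  ss_b <- sum(vapply(unique(b), function(x)
    sum(b == x) * (mean(values[b == x]) - grand)^2, numeric(1)))
  cell_means <- tapply(values, list(a, b), mean)
  ss_cells <- n_cell * sum((cell_means - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((values - cell_means[cbind(a, b)])^2)
  df_a <- length(unique(a)) - 1
  df_b <- length(unique(b)) - 1
  df_ab <- df_a * df_b
  df_err <- length(values) - length(unique(a)) * length(unique(b))
  mse <- ss_err / df_err
  c(a = (ss_a / df_a) / mse, b = (ss_b / df_b) / mse,
    ab = (ss_ab / df_ab) / mse)
}

# all permutations of 1..m (tiny m only)
combinat_perms <- function(m) {
  if (m == 1) return(list(1))
  out <- list()
  for (i in seq_len(m)) {
    for (rest in combinat_perms(m - 1)) {
      tail <- seq_len(m)[-i]
      out[[length(out) + 1L]] <- c(i, tail[rest])
    }
  }
  out
}

# total donor depletion of a simulated well (fraction of applied amount
# removed from the apical compartment by the end of the run)
donor_depletion <- function(sim_well, donor_concentration) {
  1 - utils::tail(sim_well$trajectory$Ca_end, 1) / donor_concentration
}
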