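# shared fixtures built in code

make_rail <- function(aa, c, id = "r") {
  structure(list(diet_id = id, direction = c(aa = aa, c = c)),
            class = "rail")
}

# a minimal hand-built feeding trial: one cage, constant survivors
make_feeding <- function(cage_id = "c1", diet_id = "1:10", days = 7,
                         tube1_drop = 0.5, tube2_drop = 0.3, n_alive = 5,
                         pre = 5) {
  data.frame(cage_id = cage_id, diet_id = diet_id, day = seq_len(days),
             tube1_pre_g = pre, tube1_post_g = pre - tube1_drop,
             tube2_pre_g = pre, tube2_post_g = pre - tube2_drop,
             n_alive = n_alive)
}

make_controls <- function(diet_id = "1:10", losses = rep(0.1, 7)) {
  data.frame(diet_id = diet_id, day = seq_along(losses),
             mass_loss_g = losses)
}

noiseless_config <- function(rule, target = c(aa = 0.08, c = 3), ...) {
  sim_config(rule = rule, target = target, mass_noise_sd = 0, evap_sd = 0,
             daily_death_prob = 0, ...)
}

# brute-force nearest point on a rail by two-stage grid search over s
grid_closest_s <- function(target, u, n = 1001) {
  s_max <- 2 * sqrt(sum(target^2)) / sqrt(sum(u^2)) + 1
  dist2 <- function(s) (s * u[1] - target[1])^2 + (s * u[2] - target[2])^2
  s <- seq(0, s_max, length.out = n)
  i <- which.min(dist2(s))
  lo <- s[max(1, i - 1)]; hi <- s[min(n, i + 1)]
  s2 <- seq(lo, hi, length.out = 2 * n)
  list(s = s2[which.min(dist2(s2))], s_max = s_max)
}
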