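# Shared fixtures, all built in code.

# brute-force MDA8: enumerate every complete 8-h window explicitly
mda8_bruteforce <- function(hourly) {
  best <- -Inf
  for (s in 0:16) {
    m <- mean(hourly[(s + 1):(s + 8)])
    if (m > best) best <- m
  }
  best
}

# brute-force balanced three-way ANOVA from cell-mean contrasts
anova_bruteforce <- function(tab, response = "deaths") {
  y <- tab[[response]]
  A <- factor(tab$system); B <- factor(tab$study); C <- factor(tab$population)
  g <- mean(y)
  a <- tapply(y, A, mean); b <- tapply(y, B, mean); cc <- tapply(y, C, mean)
  ab <- tapply(y, list(A, B), mean); ac <- tapply(y, list(A, C), mean)
  bc <- tapply(y, list(B, C), mean)
  nA <- nlevels(A); nB <- nlevels(B); nC <- nlevels(C)
  ss_a <- nB * nC * sum((a - g)^2)
  ss_b <- nA * nC * sum((b - g)^2)
  ss_c <- nA * nB * sum((cc - g)^2)
  dev_ab <- ab - outer(a, rep(1, nB)) - outer(rep(1, nA), b) + g
  dev_ac <- ac - outer(a, rep(1, nC)) - outer(rep(1, nA), cc) + g
  dev_bc <- bc - outer(b, rep(1, nC)) - outer(rep(1, nB), cc) + g
  ss_ab <- nC * sum(dev_ab^2)
  ss_ac <- nB * sum(dev_ac^2)
  ss_bc <- nA * sum(dev_bc^2)
  ss_tot <- sum((y - g)^2)
  ss_abc <- ss_tot - ss_a - ss_b - ss_c - ss_ab - ss_ac - ss_bc
  c(system = ss_a, study = ss_b, population = ss_c,
    `system x study` = ss_ab, `system x population` = ss_ac,
    `study x population` = ss_bc,
    `system x study x population` = ss_abc, total = ss_tot)
}

# single-cell world: one grid cell, one county, aligned rates
tiny_world <- function(rate = 0.01, persons = 100000, d = 5,
                       beta = 0.000795, n_days = 92) {
  grid <- make_grid(1, 1, bbox = c(-91, -89, 39, 41))
  delta <- make_delta(
    tibble::tibble(cell_id = 1, value = 50),
    tibble::tibble(cell_id = 1, value = 50 + d)
  )
  pop <- tibble::tibble(county_id = 1, age_lo = 0, age_hi = Inf,
                        count = persons)
  weights <- tibble::tibble(county_id = 1, cell_id = 1, weight = 1)
  rates <- tibble::tibble(endpoint = "nonaccidental mortality",
                          location_id = 1, age_lo = 0, age_hi = Inf,
                          rate = rate)
  f <- crf("fixture", "nonaccidental mortality", "MDA8", beta, 1e-4)
  list(grid = grid, delta = delta, pop = pop, weights = weights,
       rates = rates, f = f, season = o3_season(n_days = n_days))
}

# random balanced ensemble table
random_ensemble <- function(na = 3, nb = 3, nc = 3) {
  tab <- tidyr::expand_grid(
    system = paste0("s", seq_len(na)),
    study = paste0("t", seq_len(nb)),
    population = paste0("p", seq_len(nc))
  )
  tab$deaths <- stats::rnorm(nrow(tab), 100, 50)
  tab
}
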