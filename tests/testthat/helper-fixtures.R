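# shared fixture builders (everything generated in code; no stored data)

# small single-tissue box domain for analytic solver checks
oracle_box <- function(spacing = 0.2, half = 2, duration = 10) {
  grid <- sim_grid(spacing = spacing,
                   bounds = rbind(-rep(half, 3), rep(half, 3)),
                   duration = duration)
  uniform_labels(grid)
}

same_tissue <- function(p = adrenal_tissue()) {
  list(adrenal = p, fat = p, outside = p)
}

no_perfusion <- function() perfusion_properties(perfusion_rate = 0)

# noise-free 4PL standards from known parameters
make_standards <- function(a = 0.1, b = 1, c = 5, d = 2,
                           conc = c(0.5, 1, 2, 5, 10, 20, 50)) {
  data.frame(conc = conc, od = d + (a - d) / (1 + (conc / c)^b))
}

# freezing cohort data frame for n rats per condition
make_freezing_cohort <- function(n_per = 6, seed = 1, ...) {
  cfg <- cohort_config(n_per_condition = n_per, seed = seed,
                       freezing = list(...))
  set.seed(seed)
  do.call(rbind, c(
    lapply(seq_len(n_per), function(i)
      gen_freezing(cfg, sprintf("c%02d", i), "control")),
    lapply(seq_len(n_per), function(i)
      gen_freezing(cfg, sprintf("a%02d", i), "active"))))
}

# synthetic section with exactly planted per-zone particle coverage
make_planted_section <- function(coverage = c(medulla = 5, ZR = 2, ZF = 1,
                                              ZG = 0),
                                 axes = c(120, 60), dim = c(300, 160),
                                 bands = c(0.4, 0.7, 0.9), seed = 1) {
  set.seed(seed)
  ctr <- dim / 2
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2]) - ctr[1]
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE) - ctr[2]
  r <- sqrt((rr / axes[1])^2 + (cc / axes[2])^2)
  tissue <- (r <= 1) * 1L
  zone <- matrix(NA_character_, dim[1], dim[2])
  zone[r <= 1] <- "ZG"
  zone[r < bands[3]] <- "ZF"
  zone[r < bands[2]] <- "ZR"
  zone[r < bands[1]] <- "medulla"
  particles <- matrix(0L, dim[1], dim[2])
  truth <- numeric(0)
  for (z in names(coverage)) {
    px <- which(zone == z & tissue > 0)
    k <- round(length(px) * coverage[[z]] / 100)
    if (k > 0) particles[sample(px, k)] <- 1L
    truth[z] <- 100 * k / length(px)
  }
  list(mask = section_mask(tissue, particles), truth = truth, bands = bands)
}
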