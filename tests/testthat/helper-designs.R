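# shared simulated designs for model tests

make_index_data <- function(n_sites = 6, years = 2005:2017, reps = 2,
                            slope = 0, sd_site = 0.3, sd_season = 0.2,
                            sd_noise = 0.5, intercept = 5) {
  d <- expand.grid(site = paste0("S", seq_len(n_sites)), year = years,
                   season = c("cold", "warm"), rep = seq_len(reps),
                   stringsAsFactors = FALSE)
  se <- stats::setNames(rnorm(n_sites, 0, sd_site), unique(d$site))
  ss <- stats::setNames(rnorm(2, 0, sd_season), c("cold", "warm"))
  d$y <- intercept + slope * (d$year - min(d$year)) + se[d$site] +
    ss[d$season] + rnorm(nrow(d), 0, sd_noise)
  d
}
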