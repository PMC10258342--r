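# fixtures built in code; no data files

# three accessions, two replicates, one trait: accession means 5, 9, 7
toy_oneway <- function() {
  trait_dataset(data.frame(
    accession = rep(c("A", "B", "C"), each = 2),
    year = 2014L,
    replicate = rep(1:2, 3),
    trait = "SL",
    value = c(4, 6, 8, 10, 6, 8),
    stringsAsFactors = FALSE))
}

# additive zero-noise two-year dataset: accession effects -1/0/+1,
# year effects +2/-2, nr = 2  =>  sigma_g2 = 1, sigma_gy2 = 0, sigma_e2 = 0
toy_additive_across <- function() {
  g <- c(A = -1, B = 0, C = 1)
  y <- c(`2014` = 2, `2019` = -2)
  grid <- expand.grid(accession = names(g), year = c(2014L, 2019L),
                      replicate = 1:2, stringsAsFactors = FALSE)
  grid$trait <- "SL"
  grid$value <- 10 + g[grid$accession] + y[as.character(grid$year)]
  trait_dataset(grid)
}

# balanced random single-year dataset from the generator
random_single_year_ds <- function(a, nr, sigma_g2, sigma_e2, seed) {
  cfg <- sim_config(list(trait_spec("t", mu = 10, sigma_g2 = sigma_g2,
                                    sigma_e2 = sigma_e2)),
                    n_accessions = a, years = 2014L, nr = nr, seed = seed)
  simulate_dataset(cfg)
}

random_across_years_ds <- function(a, nr, sigma_g2, sigma_gy2, sigma_e2, seed,
                                   year_effects = c(-0.5, 0.5)) {
  cfg <- sim_config(list(trait_spec("t", mu = 10, sigma_g2 = sigma_g2,
                                    sigma_gy2 = sigma_gy2,
                                    sigma_e2 = sigma_e2,
                                    year_effects = year_effects)),
                    n_accessions = a, years = c(2014L, 2019L), nr = nr,
                    seed = seed)
  simulate_dataset(cfg)
}

shuffle_records <- function(ds, seed = 1) {
  set.seed(seed)
  trait_dataset(ds$records[sample.int(nrow(ds$records)), , drop = FALSE])
}
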