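# fixture builders shared across test files; everything is generated in code

# small simulated tree table with traits attached
sim_trees <- function(n = 300, seed = 1, sigma = 0.5, contamination = 0,
                      eq = "eq2", pool_n = NULL) {
  pool <- trait_table()
  if (!is.null(pool_n)) pool <- pool[seq_len(pool_n), ]
  simulate_dataset(sim_config(n_trees = n, seed = seed, sigma = sigma,
                              contamination = contamination,
                              species_pool = pool,
                              coef_model = published_model(eq)))$trees
}

# hand-built 3-row CSV with the default external header
write_toy_csv <- function(path, rows = NULL) {
  header <- "tree_id,species,dbh_cm,lcr,crown_class,sg_obs,leaf_mass_kg,mat_c,map_mm,study_id"
  if (is.null(rows)) rows <- c(
    "a1,Pinus taeda,20,0.50,dominant,0.46,5.2,15.1,1200,s1",
    "a2,Acer rubrum,10.5,0.35,intermediate,0.50,1.10,12.0,980,s1",
    "a3,Quercus alba,33.0,0.80,codominant,0.64,21.4,9.5,1100,s2")
  writeLines(c(header, rows), path)
  path
}

# brute-force normal-equations OLS oracle: solve (X'X) b = X'y by explicit
# inversion, SEs from unbiased residual variance
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  b <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = drop(b), se = sqrt(s2 * diag(XtX_inv)), sigma2 = s2,
       rss = sum(res^2))
}

r2_plain <- function(X, y) {
  f <- stats::lm.fit(cbind(1, X), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}
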