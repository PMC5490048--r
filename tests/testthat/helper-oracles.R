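# Independent oracles used by the tests.
#
# rv_descent_oracle() computes class reproductive values WITHOUT the
# gene-flow matrix: for each class it marks the genes of that class's
# members and propagates, season by season, the expected marked fraction
# of every class's gene pool, writing each biological event (who mothers
# or fathers whom, with what weight) as explicit bookkeeping.  After
# many years the pool is fully mixed and the limiting marked fraction
# phi_k, per marked founder, is proportional to class k's reproductive
# value: v_k = phi_k / u_k (normalised to v_f2 = 1).

rv_descent_oracle <- function(config, traits, years = 1e4) {
  dem <- stable_classes(config, traits, check = FALSE)
  u <- dem$u
  F1 <- config$F1; F3 <- config$F3; F5 <- dem$F5
  S_f <- config$S_f; S_m <- config$S_m
  z2 <- traits$z2
  haplo <- config$ploidy == "haplodiploid"
  serial <- config$mating == "serial_monogamy"
  nc <- length(u)

  if (config$life_cycle == "FH") {
    u3 <- u[3]; u5 <- u[5]; u7 <- u[7]
    w5 <- u5 * F5; w3 <- u3 * F3
    summer_from_spring <- function(f) {
      dau <- 0.5 * f[1] + 0.5 * f[2]
      son <- if (haplo) f[1] else 0.5 * f[1] + 0.5 * f[2]
      c(f[1], f[2], dau, dau, f[1], f[2], son)[3:7]
    }
    spring_from_summer <- function(s) {
      s3 <- s[1]; s5 <- s[3]; s6 <- s[4]; s7 <- s[5]
      fa3 <- s7                                 # summer mate of class 3
      fa5 <- if (serial) s7 else s6             # stored sperm or new mate
      mums <- (w3 * s3 + w5 * s5) / (w3 + w5)
      dads <- (w3 * fa3 + w5 * fa5) / (w3 + w5)
      f1 <- 0.5 * mums + 0.5 * dads
      son3 <- if (haplo) s3 else 0.5 * (s3 + fa3)
      son5 <- if (haplo) s5 else 0.5 * (s5 + fa5)
      wm <- c(w3 * z2, w5 * z2, S_m * u7)
      f2 <- sum(wm * c(son3, son5, s7)) / sum(wm)
      c(f1, f2)
    }
    spring_ids <- 1:2; summer_ids <- 3:7
  } else {
    u2 <- u[2]; u3 <- u[3]; u5 <- u[5]; u7 <- u[7]; u8 <- u[8]
    w5 <- u5 * F5; w3 <- u3 * F3
    summer_from_spring <- function(f) {
      dau <- 0.5 * f[1] + 0.5 * f[2]
      son <- if (haplo) f[1] else 0.5 * f[1] + 0.5 * f[2]
      c(dau, dau, f[1], f[2], f[2], son)
    }
    spring_from_summer <- function(s) {
      s3 <- s[1]; s5 <- s[3]; s6 <- s[4]; s7 <- s[5]; s8 <- s[6]
      pool2 <- (u7 * s7 + u8 * s8) / (u7 + u8)  # summer mates of class 3
      mums <- (w3 * s3 + w5 * s5) / (w3 + w5)
      dads <- (w3 * pool2 + w5 * s6) / (w3 + w5)
      f1 <- 0.5 * mums + 0.5 * dads
      f2 <- if (haplo) mums else 0.5 * mums + 0.5 * dads
      c(f1, f2)
    }
    spring_ids <- 1:2; summer_ids <- 3:8
  }

  phi <- numeric(nc)
  for (k in seq_len(nc)) {
    if (u[k] == 0) next
    if (k %in% spring_ids) {
      f_spring <- as.numeric(spring_ids == k)
      f_summer <- summer_from_spring(f_spring)
    } else {
      f_summer <- as.numeric(summer_ids == k)
    }
    for (t in seq_len(years)) {
      f_spring <- spring_from_summer(f_summer)
      f_summer <- summer_from_spring(f_spring)
    }
    phi[k] <- f_spring[1]
  }
  v <- ifelse(u > 0, phi / u, 0)
  names(v) <- names(u)
  v / (dem$alpha * v[1])          # normalisation: summer daughter RV = 1
}

# iterate the annual matrix on a random positive vector until stationary;
# the annual map alternates generations (period-2 structure), so two
# consecutive iterates are averaged to extract the stationary profile
u_iteration_oracle <- function(config, traits, iters = 1e4) {
  D <- transition_matrices(config, traits)$D
  x <- runif(nrow(D), 0.5, 1.5)
  for (i in seq_len(iters)) {
    x <- as.numeric(D %*% x)
    x <- x / sum(x)
  }
  y <- (x + as.numeric(D %*% x)) / 2
  y / y[1]
}

random_config <- function(life_cycle = c("FH", "LD")) {
  life_cycle <- sample(life_cycle, 1)
  mating <- sample(if (life_cycle == "FH")
    c("monogamy", "serial_monogamy", "polyandry")
    else c("monogamy", "polyandry"), 1)
  model_config(life_cycle, sample(c("haplodiploid", "diploid"), 1), mating,
               m_e = if (mating == "polyandry") runif(1, 1, 5) else 1,
               F1 = runif(1, 0.5, 6), F3 = runif(1, 0.5, 6),
               S_f = runif(1, 0.05, 0.95), S_m = runif(1, 0, 1),
               b = runif(1, 0, 3))
}

random_traits <- function()
  trait_state(z1 = runif(1, 0.05, 0.95), z2 = runif(1, 0.05, 0.95),
              h = runif(1, 0.05, 0.95))

fig2_config <- function()
  model_config("FH", "haplodiploid", "monogamy",
               F1 = 5, F3 = 5, S_f = 0.9, S_m = 0.6, b = 1.5)

fig3_config <- function(ploidy = "haplodiploid", mating = "monogamy",
                        m_e = 1, S_m = 0.6, life_cycle = "FH")
  model_config(life_cycle, ploidy, mating, m_e = m_e,
               F1 = 2, F3 = 2, S_f = 0.9, S_m = S_m, b = 1.5)
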