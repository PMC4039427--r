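# Shared fixture builders. Everything is generated in code; no files.

# wrap pre-made draw matrices as a pr_chains object
fake_chains <- function(..., free = c(p_max = TRUE, x_max = TRUE, alpha = TRUE)) {
  draws <- lapply(list(...), function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("p_max", "x_max", "alpha")[seq_len(ncol(m))]
    m
  })
  structure(list(draws = draws, accept = NULL, free = free,
                 config = NULL, priors = NULL,
                 n_stems = NA_integer_, n_broken = NA_integer_),
            class = "pr_chains")
}

# constant-parameter chains (every draw identical)
const_chains <- function(p_max, x_max, alpha, n = 200L, n_chains = 2L) {
  m <- matrix(rep(c(p_max, x_max, alpha), each = n), n, 3)
  do.call(fake_chains, rep(list(m), n_chains))
}

# a fixed 8-tip non-ultrametric tree for error-path tests
small_tree <- function() {
  ape::read.tree(text = "((((a:1,b:1):1,(c:1,d:1):1):1,(e:2,f:2):1):1,(g:3,h:3):1);")
}

# Brownian-motion tip values on a tree (exact, via Cholesky of the vcv)
bm_traits <- function(tree, seed, n_traits = 1L) {
  C <- ape::vcv(tree)
  L <- chol(C + diag(1e-10, nrow(C)))
  withr::with_seed(seed, {
    x <- crossprod(L, matrix(rnorm(nrow(C) * n_traits), nrow(C)))
  })
  rownames(x) <- rownames(C)
  x
}

# balanced one-way random-intercept data
oneway_data <- function(k, m, sd_b, sd_e, seed) {
  withr::with_seed(seed, {
    b <- rnorm(k, 0, sd_b)
    data.frame(plot_id = rep(sprintf("g%02d", 1:k), each = m),
               y = rep(b, each = m) + rnorm(k * m, 0, sd_e))
  })
}

# crossed family x plot Gaussian data with known components
crossed_data <- function(n_fam, n_plot, n, sd_f, sd_p, sd_e, seed,
                         sp_per_fam = 0, sd_s = 0, beta_age = 0) {
  withr::with_seed(seed, {
    fams <- sprintf("f%02d", 1:n_fam)
    plots <- sprintf("p%02d", 1:n_plot)
    b_f <- rnorm(n_fam, 0, sd_f)
    b_p <- rnorm(n_plot, 0, sd_p)
    age_z <- rnorm(n_plot)
    d <- data.frame(family_id = sample(fams, n, replace = TRUE),
                    plot_id = sample(plots, n, replace = TRUE))
    d$stand_age_z <- age_z[match(d$plot_id, plots)]
    if (sp_per_fam > 0) {
      spp <- as.vector(outer(1:sp_per_fam, fams, function(i, f) paste0(f, "_s", i)))
      b_s <- rnorm(length(spp), 0, sd_s)
      i <- sample(length(spp), n, replace = TRUE)
      d$species_id <- spp[i]
      d$family_id <- rep(fams, each = sp_per_fam)[i]
      sp_term <- b_s[i]
    } else sp_term <- 0
    d$y <- b_f[match(d$family_id, fams)] + b_p[match(d$plot_id, plots)] +
      sp_term + beta_age * d$stand_age_z + rnorm(n, 0, sd_e)
    d
  })
}

# brute-force ML profile-likelihood oracle for a family + plot crossed model:
# grid over variance ratios (gamma = sigma^2_term / sigma^2_e), residual
# variance and the GLS intercept profiled out analytically
ml_grid_oracle <- function(d, coarse = seq(0, 3, by = 0.05), fine_step = 1e-3) {
  n <- nrow(d)
  Zf <- outer(d$family_id, unique(d$family_id), `==`) * 1
  Zp <- outer(d$plot_id, unique(d$plot_id), `==`) * 1
  Kf <- tcrossprod(Zf); Kp <- tcrossprod(Zp)
  one <- rep(1, n)
  prof_ll <- function(gf, gp) {
    V <- diag(n) + gf * Kf + gp * Kp
    ch <- chol(V)
    iy <- backsolve(ch, forwardsolve(t(ch), d$y))
    i1 <- backsolve(ch, forwardsolve(t(ch), one))
    beta <- sum(i1 * d$y) / sum(i1 * one)
    r <- d$y - beta
    ir <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * ir) / n
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
  }
  scan <- function(gfs, gps) {
    best <- c(-Inf, NA, NA)
    for (gf in gfs) for (gp in gps) {
      ll <- prof_ll(gf, gp)
      if (ll > best[1]) best <- c(ll, gf, gp)
    }
    best
  }
  b <- scan(coarse, coarse)
  step <- diff(coarse[1:2])
  b <- scan(pmax(0, seq(b[2] - step, b[2] + step, by = 1e-2)),
            pmax(0, seq(b[3] - step, b[3] + step, by = 1e-2)))
  b <- scan(pmax(0, seq(b[2] - 1e-2, b[2] + 1e-2, by = fine_step)),
            pmax(0, seq(b[3] - 1e-2, b[3] + 1e-2, by = fine_step)))
  gf <- b[2]; gp <- b[3]
  V <- diag(n) + gf * Kf + gp * Kp
  ch <- chol(V)
  i1 <- backsolve(ch, forwardsolve(t(ch), one))
  beta <- sum(i1 * d$y) / sum(i1 * one)
  r <- d$y - beta
  s2 <- sum(r * backsolve(ch, forwardsolve(t(ch), r))) / n
  list(sigma2_family = gf * s2, sigma2_plot = gp * s2, sigma2_resid = s2,
       loglik = b[1])
}
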