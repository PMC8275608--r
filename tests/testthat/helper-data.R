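# small two-state dataset with intercept-only switching, used across tests
fit_toy_data <- function(n = 600, seed = 5, g12 = 0.2, g21 = 0.35,
                         mu = c(20, 90), sigma = c(15, 55)) {
  set.seed(seed)
  s <- integer(n)
  s[1] <- 1 + (runif(1) < g12 / (g12 + g21))
  for (t in 2:n)
    s[t] <- if (s[t - 1] == 1) 1 + (runif(1) < g12) else 2 - (runif(1) < g21)
  data.frame(id = "p1", burst = 1L,
             step_m = rgamma_meansd(n, mu[s], sigma[s]), truth = s)
}

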