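# Shared fixtures: reference models and small grids, built in code.

clean_lc <- function() dmps_interface_model("LC", "water")
clean_le <- function() dmps_interface_model("LE", "water")

bare_surface <- function(sigma = 3) interface_model(sigma_bottom = sigma)

# A coarse qz grid above the critical edge for quick forward checks
qz_coarse <- function(n = 40) seq(0.03, 0.5, length.out = n)

# Random 1-3 slab model with roughness in [1, smax]
random_model <- function(smax = 6) {
  N <- sample(1:3, 1)
  interface_model(
    data.frame(L = runif(N, 3, 25), rho = runif(N, 0.3, 2.5),
               sigma = runif(N, 1, smax)),
    sigma_bottom = runif(1, 1, smax))
}
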