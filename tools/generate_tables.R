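# Regenerates the synthetic stand-in coefficient tables under inst/extdata/.
# The tables are smooth, physically plausible stand-ins (log-log interpolation
# of coarse anchors, simple separable DgN shape); they are NOT literature
# tabulations. Users who need physically accurate dosimetry should replace
# them with tables interpolated from the standard references (mass
# energy-absorption coefficients of air; monoenergetic normalized glandular
# dose coefficients) in the same CSV layouts.
#
# Run from the repository root: Rscript tools/generate_tables.R

loglog_interp <- function(x0, y0, x) {
  exp(stats::approx(log(x0), log(y0), xout = log(x))$y)
}

grid_e <- seq(10, 40, by = 2.5)

# (mu_en/rho)_air in m^2/kg, anchors every 5-10 keV
mu_anchor_e <- c(10, 15, 20, 30, 40)
mu_anchor_v <- c(0.4742, 0.1334, 0.05389, 0.01537, 0.006833)
mu <- loglog_interp(mu_anchor_e, mu_anchor_v, grid_e)
write.csv(
  data.frame(energy_keV = grid_e,
             mu_en_over_rho_m2_per_kg = signif(mu, 6)),
  "inst/extdata/mu_en_air_synthetic.csv", row.names = FALSE)

# Aluminium half value layer in mm: HVL = ln 2 / mu_Al
al_anchor_e <- c(10, 15, 20, 30, 40)
al_anchor_mu_rho <- c(26.23, 7.955, 3.441, 1.128, 0.5685) # cm^2/g
rho_al <- 2.699                                            # g/cm^3
mu_al <- loglog_interp(al_anchor_e, al_anchor_mu_rho, grid_e) * rho_al
hvl_mm <- 10 * log(2) / mu_al
write.csv(
  data.frame(energy_keV = grid_e, hvl_mm = signif(hvl_mm, 6)),
  "inst/extdata/al_hvl_synthetic.csv", row.names = FALSE)

# DgN(E, t, g) in mGy/R: separable shape anchored at
# DgN(25 keV, 4.5 cm, 0.5) = 0.60, rising with energy, falling with
# thickness and glandularity.
dgn_e <- c(15, 20, 25, 30, 35)
dgn_a <- c(0.22, 0.42, 0.60, 0.78, 0.92)
dgn_t <- c(3, 4, 4.5, 5, 6, 7)
dgn_g <- c(0, 0.25, 0.5, 0.75, 1)
grid <- expand.grid(energy_keV = dgn_e, thickness_cm = dgn_t,
                    glandularity = dgn_g)
grid$dgn_mgy_per_r <- signif(
  dgn_a[match(grid$energy_keV, dgn_e)] *
    (4.5 / grid$thickness_cm)^0.6 *
    (1 - 0.25 * (grid$glandularity - 0.5)),
  6)
write.csv(grid, "inst/extdata/dgn_synthetic.csv", row.names = FALSE)

cat("wrote inst/extdata tables\n")
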