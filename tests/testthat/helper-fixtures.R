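# Shared fixtures: the printed reference table and small builders.

# Printed reference values (measured mean/sd from cryo-osmometry, n = 5;
# estimated potential; ratio; association degree for the three-component
# mixtures).
printed_table <- data.frame(
  name = c("M1", "M1a", "M1b", "M1c", "M2", "M2a", "M2b", "KCl"),
  ratio_string = c("5:12:3", "0:12:3", "5:12:0", "5:0:3", "15:12:3",
                   "25:12:3", "15:22:3", NA),
  total_M = c(1.00, 0.75, 0.85, 0.40, 1.50, 1.50, 1.50, 1.50),
  measured = c(2.93, 1.95, 2.65, 1.44, 4.88, 4.98, 4.83, 6.37),
  estimated = c(3.35, 2.23, 2.62, 1.87, 5.56, 5.84, 5.11, 6.74),
  ratio = c(0.87, 0.87, 1.01, 0.77, 0.88, 0.85, 0.95, 0.95),
  degree = c(19.5, NA, NA, NA, 18.0, 22.5, 7.5, NA),
  stringsAsFactors = FALSE
)

# Independent grid-scan oracle for the mass-action extent: scans x over
# [0, min(totals)] and locates the sign change of the residual
# x - K * prod(totals - x), refining on a second, local grid.
grid_extent_oracle <- function(totals, K, n = 1e5) {
  hi <- min(totals)
  if (K == 0 || hi == 0) return(0)
  resid <- function(x) x - K * Reduce(`*`, lapply(totals, function(t) t - x))
  xs <- seq(0, hi, length.out = n)
  r <- vapply(xs, resid, numeric(1))
  i <- which(r > 0)[1]            # residual is increasing: first positive
  if (is.na(i)) return(hi)
  if (i == 1) return(0)
  xs2 <- seq(xs[i - 1], xs[i], length.out = n)
  r2 <- vapply(xs2, resid, numeric(1))
  j <- which(r2 > 0)[1]
  (xs2[j - 1] + xs2[j]) / 2
}

# Fully retaining membrane (conservation / plateau oracles).
tight_membrane <- function() {
  membrane_spec(sigma = c("KCl" = 1, "D-Glc" = 1, "L-Gln" = 1),
                P_s = c("KCl" = 0, "D-Glc" = 0, "L-Gln" = 0))
}

default_gammas <- c("KCl" = 1.8, "D-Glc" = 1, "L-Gln" = 1.96)
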