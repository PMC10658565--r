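# shared fixtures and independent oracles

# independent volume oracle: square root of the metric-tensor determinant
metric_tensor_volume <- function(a, b, c, alpha, beta, gamma) {
  d2r <- pi / 180
  lens <- c(a, b, c)
  angs <- c(alpha, beta, gamma) * d2r
  G <- diag(lens^2)
  G[1, 2] <- G[2, 1] <- a * b * cos(angs[[3]])  # gamma between a and b
  G[1, 3] <- G[3, 1] <- a * c * cos(angs[[2]])  # beta between a and c
  G[2, 3] <- G[3, 2] <- b * c * cos(angs[[1]])  # alpha between b and c
  det_g <- det(G)
  if (det_g <= 0) return(NA_real_)
  sqrt(det_g)
}

random_valid_cell <- function() {
  repeat {
    a <- runif(1, 10, 150); b <- runif(1, 10, 150); c <- runif(1, 10, 150)
    al <- runif(1, 60, 120); be <- runif(1, 60, 120); ga <- runif(1, 60, 120)
    if (!is.na(metric_tensor_volume(a, b, c, al, be, ga)))
      return(list(a = a, b = b, c = c, alpha = al, beta = be, gamma = ga))
  }
}

# default parameter-recovery scenario: depot depletes while Ct rises to an
# appreciable fraction of Cs, so (Cs, h) are both identifiable
recovery_scenario <- function() {
  list(params = pk_parameters(t_half_days = 9.5, h = 0.03, V = 4.5,
                              Cs = 0.5, C_threshold = 0.01),
       depot = crystal_depot(M0 = 20, A0 = 10, "lamellar"),
       t_grid = seq(0, 120, length.out = 481))
}
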