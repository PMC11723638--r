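# Shared fixtures: the experiment-scale cart-pendulum and a default hand.
default_params <- function() system_params()
default_imp <- function() impedance_params(100, 10)

# trapezoid rule on a uniform grid
trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

# build a trial_record from plain kinematic vectors with filler dynamics
make_record <- function(t, xd, x = cumsum(c(0, diff(t) * head(xd, -1))),
                        L = max(x), rate = 1 / median(diff(t))) {
  n <- length(t)
  trial_record(t = t, F = numeric(n), x = x, xd = xd, xdd = numeric(n),
               phi = numeric(n), phid = numeric(n), phidd = numeric(n),
               rate = rate, meta = list(displacement = L))
}

# downsample a fine state_trajectory into a 120 Hz trial_record
traj_to_record <- function(tr, L, by = 10L) {
  i <- seq(1L, length(tr$t), by = by)
  trial_record(t = tr$t[i], F = tr$F[i], x = tr$x[i], xd = tr$x_dot[i],
               xdd = tr$x_ddot[i], phi = tr$phi[i], phid = tr$phi_dot[i],
               phidd = tr$phi_ddot[i], rate = 1 / (tr$step * by),
               meta = list(displacement = L))
}
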