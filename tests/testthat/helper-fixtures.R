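# Shared fixtures: short simulation configs and the extended-precision
# GHK reference table.

short_config <- function(duration = 300, ...) {
  simulation_config(duration = duration, ...)
}

# Reference GHK flux values computed once with 50-digit arithmetic
# (sympy evalf) for P = 1e-3 cm/s at T = 294.15 K; J scales linearly in P.
ghk_reference <- function() {
  tab <- read.csv(text = "dpsi,H_i,H_o,J
-0.2,2.5118864315095801e-11,1.2589254117941672e-10,9.9366742800254562e-13
-0.2,1e-10,1e-10,7.8906162756544699e-13
-0.2,5.0118723362727228e-11,2.5118864315095801e-11,1.9812946798585275e-13
-0.045,2.5118864315095801e-11,1.2589254117941672e-10,2.6000175754915513e-13
-0.045,1e-10,1e-10,1.7753886620222557e-13
-0.045,5.0118723362727228e-11,2.5118864315095801e-11,3.5542449785228144e-14
-1e-05,2.5118864315095801e-11,1.2589254117941672e-10,1.0080346749782791e-13
-1e-05,1e-10,1e-10,3.945308137827235e-17
-1e-05,5.0118723362727228e-11,2.5118864315095801e-11,-2.4985017598563148e-14
0.045,2.5118864315095801e-11,1.2589254117941672e-10,-8.1021796018477726e-15
0.045,1e-10,1e-10,-1.7753886620222557e-13
0.045,5.0118723362727228e-11,2.5118864315095801e-11,-9.8033510335884239e-14
1e-05,2.5118864315095801e-11,1.2589254117941672e-10,1.0074388884512769e-13
1e-05,1e-10,1e-10,-3.945308137827235e-17
1e-05,5.0118723362727228e-11,2.5118864315095801e-11,-2.5014701145256728e-14
0.2,2.5118864315095801e-11,1.2589254117941672e-10,-1.9790562600191173e-13
0.2,1e-10,1e-10,-7.8906162756544699e-13
0.2,5.0118723362727228e-11,2.5118864315095801e-11,-3.9554146588575784e-13")
  tab$P <- 1e-3
  tab
}

# one-vesicle noiseless render of a short simulated trace
noiseless_fixture <- function(duration = 50, position = c(64, 64),
                              seed = 3) {
  tr <- simulate_acidification(short_config(duration = duration))
  img <- image_render_config(positions = matrix(position, 1, 2),
                             poisson_scale = 0, read_sd = 0, seed = seed)
  list(trace = tr,
       stack = render_timelapse(list(tr), calibration_curve(), img),
       img = img)
}
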