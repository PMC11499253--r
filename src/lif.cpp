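// Euler integration of a current-based excitatory LIF network with a single
// graded feedback-inhibition variable and per-neuron synaptic time constants.
// Membrane:  tau_m dx/dt = -x + g*(W p - g_inh I_inh) + w s(t) + eta
// Inhibition: tau_I dI/dt = -I + mean(r)
// Synapse:    tau_s,i dp_i/dt = -p_i + r_i
// On x_i > theta: x_i <- 0 and r_i = 1 for a fixed 1 ms of simulated
// time (one step at the default dt; proportionally more steps when dt is
// refined, so the synaptic drive per spike is independent of the step).
// Gaussian current noise eta ~ N(0, noise_sd^2) is drawn each step from an
// internal mt19937_64 generator seeded explicitly, so runs are reproducible
// and fast independent of R's RNG.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List lif_simulate_cpp(const arma::sp_mat& W,   // N x N, W(i,j): j -> i
                            const arma::vec& w_in,   // N input weights
                            const arma::vec& s,      // length T_steps input
                            const arma::vec& tau_s,  // N synaptic tau (s)
                            double tau_m, double tau_I,
                            double g, double g_inh, double theta,
                            double dt, double noise_sd,
                            int record_every, int seed) {
  const uword N = W.n_rows;
  const uword T = s.n_elem;
  const uword nrec = (T + record_every - 1) / record_every;

  vec x(N, fill::zeros), p(N, fill::zeros);
  double I_inh = 0.0;
  mat p_rec(N, nrec, fill::zeros);
  mat x_rec(N, nrec, fill::zeros);
  mat spk_rec(N, nrec, fill::zeros);  // spike counts per record bin
  vec Iinh_rec(nrec, fill::zeros);

  const double am = dt / tau_m, aI = dt / tau_I;
  vec ap = dt / tau_s;  // per neuron
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const int pulse_steps = std::max(1, (int)std::lround(0.001 / dt));

  vec r(N, fill::zeros);
  std::vector<int> pulse_left(N, 0);
  for (uword t = 0; t < T; ++t) {
    vec drive = g * (vec(W * p) - g_inh * I_inh) + w_in * s(t);
    if (noise_sd > 0) {
      for (uword i = 0; i < N; ++i) drive(i) += noise_sd * gauss(rng);
    }
    x += am * (-x + drive);
    if (!x.is_finite()) {
      Rcpp::stop("non-finite membrane potential at step %d", (int)t);
    }
    uword rb = t / record_every;
    double ractive = 0.0;
    for (uword i = 0; i < N; ++i) {
      if (x(i) > theta) {
        x(i) = 0.0;
        pulse_left[i] = pulse_steps;
        spk_rec(i, rb) += 1.0;
      }
      if (pulse_left[i] > 0) {
        r(i) = 1.0; --pulse_left[i]; ractive += 1.0;
      } else {
        r(i) = 0.0;
      }
    }
    I_inh += aI * (-I_inh + ractive / N);
    p += ap % (r - p);

    if ((t + 1) % record_every == 0 || t == T - 1) {
      p_rec.col(rb) = p;
      x_rec.col(rb) = x;
      Iinh_rec(rb) = I_inh;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("p") = p_rec, Rcpp::Named("x") = x_rec,
    Rcpp::Named("spikes") = spk_rec, Rcpp::Named("I_inh") = Iinh_rec,
    Rcpp::Named("dt") = dt, Rcpp::Named("record_every") = record_every);
}
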