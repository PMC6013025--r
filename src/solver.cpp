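#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pseudo-steady-state reaction-diffusion solve on a regular 2D lattice.
//
// Discretisation: cell-centred finite volumes, spacing h; row 0 sits on the
// no-flux substratum (mirror boundary), columns wrap periodically, and every
// row >= clamp_row0 is a Dirichlet region held at the solute's bulk value.
//
// Nonlinearity: damped Picard. For each solute the net source is split as
// P - L*C, where consumption routed through a Monod factor on the solute
// itself contributes to the diagonal L (semi-implicit, keeps iterates
// non-negative) and everything else enters the constant part P. P and L are
// refreshed from the current fields every outer iteration; in between, a few
// red-black SOR sweeps relax the linearised equation. Concentrations driven
// negative by concentration-independent sinks (antibiotic detoxification)
// are truncated to zero; there the pointwise residual cannot vanish (the
// depleted region is an obstacle-problem free boundary) so convergence is
// measured on the relative field change.

struct Reaction {
  int actor;                       // 0 = R, 1 = S
  double max_rate;
  std::vector<int> monod_idx;      // solute indices, 0-based
  std::vector<double> monod_K;
  std::vector<int> inhib_idx;
  std::vector<double> inhib_Ki;
  std::vector<int> st_idx;         // solutes with non-zero stoichiometry
  std::vector<double> st_coef;
};

static std::vector<Reaction> unpack_reactions(const List& reactions) {
  std::vector<Reaction> out;
  for (int k = 0; k < reactions.size(); ++k) {
    List rl = reactions[k];
    Reaction r;
    r.actor = as<int>(rl["actor"]);
    r.max_rate = as<double>(rl["max_rate"]);
    IntegerVector mi = rl["monod_idx"]; NumericVector mk = rl["monod_K"];
    for (int i = 0; i < mi.size(); ++i) {
      r.monod_idx.push_back(mi[i]); r.monod_K.push_back(mk[i]);
    }
    IntegerVector ii = rl["inhib_idx"]; NumericVector ik = rl["inhib_Ki"];
    for (int i = 0; i < ii.size(); ++i) {
      r.inhib_idx.push_back(ii[i]); r.inhib_Ki.push_back(ik[i]);
    }
    IntegerVector si = rl["stoich_idx"]; NumericVector sc = rl["stoich_coef"];
    for (int i = 0; i < si.size(); ++i) {
      r.st_idx.push_back(si[i]); r.st_coef.push_back(sc[i]);
    }
    out.push_back(r);
  }
  return out;
}

// [[Rcpp::export]]
List pss_solve_cpp(List fields, NumericMatrix X_R, NumericMatrix X_S,
                   List reactions, NumericVector D, NumericVector bulk,
                   double h, int clamp_row, double tol, int max_outer,
                   double omega, int inner_sweeps, LogicalVector solve_mask) {
  const int ns = fields.size();
  const int nrow = X_R.nrow(), ncol = X_R.ncol();
  const int top = std::min(clamp_row - 1, nrow); // active rows: 0 .. top-1

  std::vector<NumericMatrix> C(ns);
  for (int s = 0; s < ns; ++s) {
    C[s] = clone(as<NumericMatrix>(fields[s]));
    // Dirichlet region at bulk
    for (int r = top; r < nrow; ++r)
      for (int c = 0; c < ncol; ++c) C[s](r, c) = bulk[s];
  }

  std::vector<Reaction> rx = unpack_reactions(reactions);
  const double ih2 = 1.0 / (h * h);

  // scale per solute for relative-change convergence
  std::vector<double> scale(ns);
  auto refresh_scale = [&](int s) {
    double m = bulk[s];
    for (int r = 0; r < top; ++r)
      for (int c = 0; c < ncol; ++c) m = std::max(m, C[s](r, c));
    scale[s] = std::max(m, 1e-300);
  };
  for (int s = 0; s < ns; ++s) refresh_scale(s);

  std::vector<double> P(top * ncol), L(top * ncol);
  double max_change = R_PosInf;
  int outer = 0;
  bool converged = false;

  for (outer = 1; outer <= max_outer; ++outer) {
    max_change = 0.0;
    for (int s = 0; s < ns; ++s) {
      if (!solve_mask[s] || top == 0) continue;
      std::fill(P.begin(), P.end(), 0.0);
      std::fill(L.begin(), L.end(), 0.0);
      // assemble source split P - L*C for solute s
      for (size_t k = 0; k < rx.size(); ++k) {
        const Reaction& r = rx[k];
        double coef = 0.0; bool touches = false;
        for (size_t q = 0; q < r.st_idx.size(); ++q)
          if (r.st_idx[q] == s) { coef = r.st_coef[q]; touches = true; }
        if (!touches || coef == 0.0) continue;
        // does the reaction carry a Monod factor on s itself?
        int self_monod = -1;
        for (size_t q = 0; q < r.monod_idx.size(); ++q)
          if (r.monod_idx[q] == s) self_monod = (int)q;
        const NumericMatrix& X = (r.actor == 0) ? X_R : X_S;
        for (int c = 0; c < ncol; ++c) {
          for (int rr = 0; rr < top; ++rr) {
            double x = X(rr, c);
            if (x == 0.0) continue;
            double f = r.max_rate * x;
            double selfdenom = 1.0;
            for (size_t q = 0; q < r.monod_idx.size(); ++q) {
              double Cm = C[r.monod_idx[q]](rr, c);
              double den = Cm + r.monod_K[q];
              if ((int)q == self_monod && coef < 0.0) selfdenom = den;
              else f *= Cm / den;
            }
            for (size_t q = 0; q < r.inhib_idx.size(); ++q) {
              double Ci = C[r.inhib_idx[q]](rr, c);
              f *= r.inhib_Ki[q] / (Ci + r.inhib_Ki[q]);
            }
            int node = c * top + rr;
            if (coef < 0.0 && self_monod >= 0) {
              L[node] += (-coef) * f / selfdenom;   // implicit self-consumption
            } else {
              P[node] += coef * f;                  // production or constant sink
            }
          }
        }
      }
      // red-black SOR sweeps on the linearised equation
      const double Ds = D[s];
      NumericMatrix& F = C[s];
      for (int sw = 0; sw < inner_sweeps; ++sw) {
        for (int colour = 0; colour < 2; ++colour) {
          for (int c = 0; c < ncol; ++c) {
            int cl = (c == 0) ? ncol - 1 : c - 1;
            int cr = (c == ncol - 1) ? 0 : c + 1;
            for (int rr = (c + colour) % 2; rr < top; rr += 2) {
              double nb = F(rr, cl) + F(rr, cr) + F(rr + 1 <= nrow - 1 ? rr + 1 : rr, c);
              int nn = 3;
              if (rr > 0) { nb += F(rr - 1, c); nn = 4; }
              int node = c * top + rr;
              double denom = nn * Ds * ih2 + L[node];
              double cnew = (Ds * ih2 * nb + P[node]) / denom;
              double cold = F(rr, c);
              double cval = cold + omega * (cnew - cold);
              if (cval < 0.0) cval = 0.0;
              F(rr, c) = cval;
              double ch = std::fabs(cval - cold) / scale[s];
              if (ch > max_change) max_change = ch;
            }
          }
        }
      }
      refresh_scale(s);
    }
    if (max_change < tol) { converged = true; break; }
  }

  List out_fields(ns);
  for (int s = 0; s < ns; ++s) out_fields[s] = C[s];
  out_fields.attr("names") = fields.attr("names");
  return List::create(_["fields"] = out_fields,
                      _["outer_iterations"] = outer,
                      _["max_rel_change"] = max_change,
                      _["converged"] = converged);
}
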