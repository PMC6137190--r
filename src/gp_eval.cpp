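#include <Rcpp.h>
using namespace Rcpp;

// Prefix-encoded expression trees.
// code[i]: 1 add, 2 sub, 3 mul, 4 pdiv, 5 min, 6 max, 7 neg, 8 ifgt,
//          0 constant (value consumed from `consts` in encounter order),
//          100 + j  feature variable, column j (1-based) of X.

static void eval_node(const int* code, const double* consts,
                      int& pos, int& cpos,
                      const NumericMatrix& X, std::vector<double>& out) {
  const int n = X.nrow();
  const int op = code[pos++];
  if (op >= 100) {
    const int j = op - 100 - 1;
    for (int i = 0; i < n; ++i) out[i] = X(i, j);
    return;
  }
  if (op == 0) {
    const double v = consts[cpos++];
    std::fill(out.begin(), out.end(), v);
    return;
  }
  switch (op) {
  case 7: { // neg
    eval_node(code, consts, pos, cpos, X, out);
    for (int i = 0; i < n; ++i) out[i] = -out[i];
    return;
  }
  case 8: { // ifgt(a, b, c, d): a > b ? c : d
    std::vector<double> a(n), b(n), c(n);
    eval_node(code, consts, pos, cpos, X, a);
    eval_node(code, consts, pos, cpos, X, b);
    eval_node(code, consts, pos, cpos, X, c);
    eval_node(code, consts, pos, cpos, X, out); // d in `out`
    for (int i = 0; i < n; ++i) if (a[i] > b[i]) out[i] = c[i];
    return;
  }
  default: { // binary ops
    std::vector<double> a(n);
    eval_node(code, consts, pos, cpos, X, a);
    eval_node(code, consts, pos, cpos, X, out);
    switch (op) {
    case 1: for (int i = 0; i < n; ++i) out[i] = a[i] + out[i]; break;
    case 2: for (int i = 0; i < n; ++i) out[i] = a[i] - out[i]; break;
    case 3: for (int i = 0; i < n; ++i) out[i] = a[i] * out[i]; break;
    case 4: for (int i = 0; i < n; ++i)
              out[i] = (out[i] == 0.0) ? 1.0 : a[i] / out[i];
            break;
    case 5: for (int i = 0; i < n; ++i) out[i] = std::min(a[i], out[i]); break;
    case 6: for (int i = 0; i < n; ++i) out[i] = std::max(a[i], out[i]); break;
    default: stop("unknown opcode");
    }
    return;
  }
  }
}

// [[Rcpp::export]]
NumericVector gp_eval_prefix(IntegerVector code, NumericVector consts,
                             NumericMatrix X) {
  std::vector<double> out(X.nrow());
  int pos = 0, cpos = 0;
  eval_node(code.begin(), consts.begin(), pos, cpos, X, out);
  if (pos != code.size()) stop("malformed prefix code");
  return wrap(out);
}

// Balanced-accuracy-with-parsimony fitness for a whole population in one call.
// y: 0/1 labels. sizes: node counts. fitness = (TPR + TNR)/2 - alpha * size.
// [[Rcpp::export]]
NumericVector gp_fitness_batch(List codes, List consts, NumericMatrix X,
                               IntegerVector y, double alpha,
                               IntegerVector sizes) {
  const int m = codes.size();
  const int n = X.nrow();
  NumericVector fit(m);
  std::vector<double> out(n);
  for (int k = 0; k < m; ++k) {
    IntegerVector code = codes[k];
    NumericVector cst = consts[k];
    int pos = 0, cpos = 0;
    eval_node(code.begin(), cst.begin(), pos, cpos, X, out);
    if (pos != code.size()) stop("malformed prefix code");
    int tp = 0, fn = 0, tn = 0, fp = 0;
    for (int i = 0; i < n; ++i) {
      const bool pred = out[i] > 0.0;
      if (y[i] == 1) { if (pred) ++tp; else ++fn; }
      else           { if (pred) ++fp; else ++tn; }
    }
    const double tpr = (tp + fn) > 0 ? (double)tp / (tp + fn) : 0.0;
    const double tnr = (tn + fp) > 0 ? (double)tn / (tn + fp) : 0.0;
    fit[k] = 0.5 * (tpr + tnr) - alpha * sizes[k];
  }
  return fit;
}
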