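#include <Rcpp.h>
using namespace Rcpp;

// Minimisation with a random element (Pocock-Simon range variant).
// Counts are laid out as one matrix: rows index (factor, level) pairs across
// all stratification factors, columns index the arms active in the current
// stage.  The imbalance score a new patient would create on arm a is the sum,
// over factors, of the count of same-level patients already on a (plus the
// candidate patient), normalised by the arm's allocation weight.  The
// minimising arm is selected with probability p; otherwise one of the
// remaining arms is selected uniformly.  Ties among minima are broken
// uniformly before the random element is applied.

static int minimisation_choose(const IntegerMatrix& counts,
                               const IntegerVector& rows,
                               const NumericVector& weights,
                               double p_random,
                               NumericVector& scores_out) {
  const int n_arms = counts.ncol();
  const int n_fac = rows.size();
  for (int a = 0; a < n_arms; ++a) {
    double s = 0.0;
    for (int f = 0; f < n_fac; ++f) s += (counts(rows[f], a) + 1.0) / weights[a];
    scores_out[a] = s;
  }
  double smin = scores_out[0];
  for (int a = 1; a < n_arms; ++a) if (scores_out[a] < smin) smin = scores_out[a];
  // indices within numerical tie tolerance of the minimum
  std::vector<int> minima;
  for (int a = 0; a < n_arms; ++a)
    if (scores_out[a] <= smin + 1e-12) minima.push_back(a);
  int pick;
  if (minima.size() == 1) {
    pick = minima[0];
  } else {
    int j = (int)(unif_rand() * minima.size());
    if (j >= (int)minima.size()) j = minima.size() - 1;
    pick = minima[j];
  }
  if (unif_rand() >= p_random) {
    // deviate: uniform over the other arms
    int j = (int)(unif_rand() * (n_arms - 1));
    if (j >= n_arms - 1) j = n_arms - 2;
    pick = (j < pick) ? j : j + 1;
  }
  return pick;
}

// [[Rcpp::export]]
List cpp_minimisation_step(IntegerMatrix counts, IntegerVector rows,
                           NumericVector weights, double p_random) {
  NumericVector scores(counts.ncol());
  int pick = minimisation_choose(counts, rows, weights, p_random, scores);
  return List::create(_["arm"] = pick + 1, _["scores"] = scores);
}

struct Trigger {
  int type;        // 0 = none, 1 = arm recruitment count, 2 = calendar time
  int arm;         // 0-based global arm index (type 1)
  int n;           // count threshold (type 1)
  int from_stage;  // 0-based first stage counted (type 1)
  double time;     // years (type 2)
};

static Trigger parse_trigger(List tr) {
  Trigger t;
  t.type = as<int>(tr["type"]);
  t.arm = tr.containsElementNamed("arm") ? as<int>(tr["arm"]) : -1;
  t.n = tr.containsElementNamed("n") ? as<int>(tr["n"]) : 0;
  t.from_stage = tr.containsElementNamed("from_stage") ? as<int>(tr["from_stage"]) : 0;
  t.time = tr.containsElementNamed("time") ? as<double>(tr["time"]) : 0.0;
  return t;
}

static bool trigger_fires(const Trigger& t, const IntegerMatrix& arm_by_stage,
                          double now) {
  if (t.type == 1) {
    int tot = 0;
    for (int s = t.from_stage; s < arm_by_stage.nrow(); ++s)
      tot += arm_by_stage(s, t.arm);
    return tot >= t.n;
  }
  if (t.type == 2) return now >= t.time;
  return false;
}

// Sequential staged recruitment: walk the patient stream, fire stage
// transitions the first time their entry trigger holds (minimisation counts
// are reset at each transition), stop recruitment when the stop rule fires.
// profile_rows holds, per patient and factor, the 0-based row of the
// patient's level in the minimisation count matrix.
// [[Rcpp::export]]
List cpp_run_recruitment(IntegerMatrix profile_rows, NumericVector entry_times,
                         List stages, List stop_rule, int n_arms,
                         int n_level_rows, double p_random) {
  const int n_max = profile_rows.nrow();
  const int n_fac = profile_rows.ncol();
  const int n_stages = stages.size();

  std::vector<IntegerVector> active(n_stages);
  std::vector<NumericVector> weights(n_stages);
  std::vector<Trigger> entry(n_stages);
  for (int s = 0; s < n_stages; ++s) {
    List st = stages[s];
    active[s] = as<IntegerVector>(st["active"]);   // 0-based global arm ids
    weights[s] = as<NumericVector>(st["weights"]);
    entry[s] = parse_trigger(as<List>(st["trigger"]));
  }
  Trigger stop = parse_trigger(stop_rule);

  IntegerMatrix arm_by_stage(n_stages, n_arms);
  IntegerVector arm_out(n_max, NA_INTEGER);
  IntegerVector stage_out(n_max, NA_INTEGER);
  IntegerVector stage_first(n_stages, NA_INTEGER);  // 1-based patient index

  int cur = 0;
  stage_first[0] = 1;
  IntegerMatrix counts(n_level_rows, active[0].size());
  NumericVector scores(n_arms);
  IntegerVector rows(n_fac);
  bool stopped = false;
  int n_recruited = 0;

  for (int i = 0; i < n_max; ++i) {
    double now = entry_times[i];
    while (cur + 1 < n_stages &&
           trigger_fires(entry[cur + 1], arm_by_stage, now)) {
      ++cur;
      stage_first[cur] = i + 1;
      counts = IntegerMatrix(n_level_rows, active[cur].size());  // reset
    }
    if (trigger_fires(stop, arm_by_stage, now)) { stopped = true; break; }

    for (int f = 0; f < n_fac; ++f) rows[f] = profile_rows(i, f);
    NumericVector sc(active[cur].size());
    int pick = minimisation_choose(counts, rows, weights[cur], p_random, sc);
    for (int f = 0; f < n_fac; ++f) counts(rows[f], pick) += 1;
    int garm = active[cur][pick];
    arm_by_stage(cur, garm) += 1;
    arm_out[i] = garm + 1;       // 1-based global arm id
    stage_out[i] = cur + 1;
    n_recruited = i + 1;
  }

  return List::create(_["arm"] = arm_out, _["stage"] = stage_out,
                      _["n"] = n_recruited, _["stopped"] = stopped,
                      _["stage_first"] = stage_first,
                      _["arm_by_stage"] = arm_by_stage,
                      _["last_stage"] = cur + 1);
}
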