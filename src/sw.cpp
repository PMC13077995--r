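#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gotoh affine local alignment with full traceback.
// Gap of length k costs gap_open + k * gap_ext (Biostrings convention).
// One packed traceback byte per cell:
//   bits 0-1: H source (0 = stop at score 0, 1 = diagonal, 2 = E, 3 = F)
//   bit 2: E extended from E (else opened from H)   E consumes reference
//   bit 3: F extended from F (else opened from H)   F consumes query

// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string query, std::string ref,
              int match = 1, int mismatch = -2,
              int gap_open = 4, int gap_ext = 2) {
  const int m = (int) query.size();
  const int n = (int) ref.size();
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_ext;

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fv(n + 1, NEG);
  std::vector<uint8_t> TB((size_t)(m + 1) * (n + 1), 0);
  const char* q = query.data();
  const char* r = ref.data();

  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    int Ev = NEG;
    Hcur[0] = 0;
    const char qc = q[i - 1];
    uint8_t* tb = &TB[(size_t) i * (n + 1)];
    const int* hp = Hprev.data();
    int* hc = Hcur.data();
    int* fv = Fv.data();
    for (int j = 1; j <= n; ++j) {
      uint8_t t;
      // E: gap consuming reference
      const int e_open = hc[j - 1] - open_cost;
      const int e_ext = Ev - gap_ext;
      if (e_ext > e_open) { Ev = e_ext; t = 4; }
      else                { Ev = e_open; t = 0; }
      // F: gap consuming query
      const int f_open = hp[j] - open_cost;
      const int f_ext = fv[j] - gap_ext;
      int f;
      if (f_ext > f_open) { f = f_ext; t |= 8; }
      else                { f = f_open; }
      fv[j] = f;
      // H
      const int diag = hp[j - 1] + ((qc == r[j - 1]) ? match : mismatch);
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (Ev > h)   { h = Ev;   src = 2; }
      if (f > h)    { h = f;    src = 3; }
      hc[j] = h;
      tb[j] = t | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  if (best <= 0) {
    IntegerMatrix g0(0, 4);
    colnames(g0) = CharacterVector::create("type", "q_pos", "r_pos", "len");
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["r_start"] = NA_INTEGER,
                        _["r_end"] = NA_INTEGER, _["n_match"] = 0,
                        _["gaps"] = g0);
  }

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  int n_match = 0;
  // gap runs: type 1 = deletion (consumes ref), 2 = insertion (consumes query)
  std::vector<int> gtype, gq, gr, glen;
  int run_type = 0, run_len = 0;

  auto close_run = [&](int qi, int rj) {
    if (run_len > 0) {
      gtype.push_back(run_type);
      gq.push_back(qi);
      gr.push_back(rj);
      glen.push_back(run_len);
      run_type = 0; run_len = 0;
    }
  };

  while (true) {
    const uint8_t t = TB[(size_t) i * (n + 1) + j];
    if (state == 0) {
      const uint8_t src = t & 3;
      if (src == 0) { close_run(i, j); break; }
      if (src == 1) {
        close_run(i, j);
        if (q[i - 1] == r[j - 1]) ++n_match;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: gap consumes reference
      if (run_type != 1) { close_run(i, j); run_type = 1; }
      ++run_len;
      const bool ext = (t & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else { // F: gap consumes query
      if (run_type != 2) { close_run(i, j); run_type = 2; }
      ++run_len;
      const bool ext = (t & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }

  const int q_start = i, r_start = j;
  // close_run fires after a run's steps have decremented i/j, so recorded
  // coordinates are already the forward-orientation run starts
  const int ng = (int) gtype.size();
  IntegerMatrix gaps(ng, 4);
  for (int k = 0; k < ng; ++k) {
    const int src = ng - 1 - k; // runs collected backwards; emit forward
    gaps(k, 0) = gtype[src];
    gaps(k, 1) = gq[src];
    gaps(k, 2) = gr[src];
    gaps(k, 3) = glen[src];
  }
  colnames(gaps) = CharacterVector::create("type", "q_pos", "r_pos", "len");

  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = bi,
                      _["r_start"] = r_start, _["r_end"] = bj,
                      _["n_match"] = n_match, _["gaps"] = gaps);
}
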