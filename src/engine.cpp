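// Continuous-time Gillespie engine for an endemic clade radiating over a
// banded mountain lattice.  Populations (one per species per cell) undergo
// colonization (rate gamma, optionally filtered by local-adaptation
// fitness), extirpation (rate mu) and speciation (per-band rate lambda).
// R owns the RNG: all draws go through unif_rand/norm_rand/exp_rand so a
// set.seed() in R makes whole runs reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// event kinds in the log
enum EventKind {
  EV_COLONIZE = 0,       // successful range expansion
  EV_COLONIZE_BLOCKED,   // no candidate cell (saturated / none adjacent)
  EV_COLONIZE_REJECTED,  // candidate drawn but fitness rejection
  EV_EXTIRPATE,          // local extinction of one population
  EV_SPECIES_EXTINCT,    // last population extirpated
  EV_SPECIATE,           // population buds off as a new species
  EV_ANAGENESIS          // single-population parent replaced by its child
};

struct SpeciesRec {
  int origin_band;
  int parent;
  std::vector<int> cells;           // occupied cells (unordered)
  std::unordered_set<int> cellset;  // membership mirror of `cells`
  std::vector<int> bandcnt;         // populations per band
};

struct Sim {
  // landscape
  int ncell = 0, nbands = 0;
  std::vector<int> band;
  std::vector<double> temp;
  std::vector<int> adj_ptr, adj;  // CSR adjacency, 0-based
  std::vector<double> bandK, bandLam;

  // parameters
  double gamma_ = 1.0, mu = 0.2, V = 5.0;
  bool local_adapt = false;

  // state
  double clock_ = 0.0;
  long long n_events = 0;
  std::vector<int> occ;  // species count per cell
  std::vector<int> pop_sp, pop_cell;
  std::vector<double> pop_tp;
  std::vector<std::vector<int>> band_pops;  // population indices per band
  std::vector<int> pop_bandpos;             // index of pop in its band list
  std::unordered_map<int, SpeciesRec> species;
  int next_species = 1;
  std::vector<int> band_rich;  // species with >= 1 population per band

  // event log
  bool log_events = false;
  std::vector<double> ev_time;
  std::vector<int> ev_kind, ev_sp, ev_parent, ev_src, ev_dst;

  // sampled richness / mismatch trajectory
  double sample_dt = 1.0, next_sample = 0.0;
  std::vector<double> ts_time;
  std::vector<int> ts_reg;
  std::vector<std::vector<int>> ts_band;
  std::vector<std::vector<double>> ts_mismatch;

  // scratch for candidate collection
  std::vector<int> cand;
  std::vector<int> seen_stamp;
  int stamp = 0;

  void log(double t, int kind, int sp, int parent, int src, int dst) {
    if (!log_events) return;
    ev_time.push_back(t);
    ev_kind.push_back(kind);
    ev_sp.push_back(sp);
    ev_parent.push_back(parent);
    ev_src.push_back(src);
    ev_dst.push_back(dst);
  }

  void bump_band(SpeciesRec& rec, int b, int delta) {
    int before = rec.bandcnt[b];
    rec.bandcnt[b] += delta;
    if (before == 0 && rec.bandcnt[b] > 0) band_rich[b] += 1;
    if (before > 0 && rec.bandcnt[b] == 0) band_rich[b] -= 1;
  }

  int add_population(int sp, int cell, double tp) {
    int idx = (int)pop_sp.size();
    pop_sp.push_back(sp);
    pop_cell.push_back(cell);
    pop_tp.push_back(tp);
    int b = band[cell];
    band_pops[b].push_back(idx);
    pop_bandpos.push_back((int)band_pops[b].size() - 1);
    occ[cell] += 1;
    SpeciesRec& rec = species.at(sp);
    rec.cells.push_back(cell);
    rec.cellset.insert(cell);
    bump_band(rec, b, +1);
    return idx;
  }

  // removes population `idx`; returns true if its species went extinct
  bool remove_population(int idx) {
    int sp = pop_sp[idx], cell = pop_cell[idx];
    int b = band[cell];
    occ[cell] -= 1;
    SpeciesRec& rec = species.at(sp);
    for (size_t i = 0; i < rec.cells.size(); ++i) {
      if (rec.cells[i] == cell) {
        rec.cells[i] = rec.cells.back();
        rec.cells.pop_back();
        break;
      }
    }
    rec.cellset.erase(cell);
    bump_band(rec, b, -1);

    // drop from its band list (swap-remove)
    std::vector<int>& bl = band_pops[b];
    int pos = pop_bandpos[idx];
    bl[pos] = bl.back();
    pop_bandpos[bl[pos]] = pos;
    bl.pop_back();

    // swap-remove from the population arrays
    int last = (int)pop_sp.size() - 1;
    if (idx != last) {
      pop_sp[idx] = pop_sp[last];
      pop_cell[idx] = pop_cell[last];
      pop_tp[idx] = pop_tp[last];
      pop_bandpos[idx] = pop_bandpos[last];
      band_pops[band[pop_cell[idx]]][pop_bandpos[idx]] = idx;
    }
    pop_sp.pop_back();
    pop_cell.pop_back();
    pop_tp.pop_back();
    pop_bandpos.pop_back();

    if (rec.cells.empty()) {
      species.erase(sp);
      return true;
    }
    return false;
  }

  double total_rate() const {
    double tot = 0.0;
    for (int b = 0; b < nbands; ++b)
      tot += band_pops[b].size() * (gamma_ + mu + bandLam[b]);
    return tot;
  }

  void record_sample(double t) {
    ts_time.push_back(t);
    ts_reg.push_back((int)species.size());
    std::vector<double> mism(nbands, 0.0);
    std::vector<int> cnt(nbands, 0);
    for (size_t i = 0; i < pop_sp.size(); ++i) {
      int b = band[pop_cell[i]];
      mism[b] += std::fabs(temp[pop_cell[i]] - pop_tp[i]);
      cnt[b] += 1;
    }
    for (int b = 0; b < nbands; ++b) {
      ts_band[b].push_back(band_rich[b]);
      ts_mismatch[b].push_back(cnt[b] ? mism[b] / cnt[b] : NA_REAL);
    }
  }

  void samples_until(double t) {
    while (next_sample <= t) {
      record_sample(next_sample);
      next_sample += sample_dt;
    }
  }

  void do_colonization(int idx) {
    int sp = pop_sp[idx];
    int src = pop_cell[idx];
    double tp = pop_tp[idx];
    SpeciesRec& rec = species.at(sp);

    cand.clear();
    ++stamp;
    for (int c : rec.cells) {
      for (int k = adj_ptr[c]; k < adj_ptr[c + 1]; ++k) {
        int d = adj[k];
        if (seen_stamp[d] == stamp) continue;
        seen_stamp[d] = stamp;
        if (occ[d] >= bandK[band[d]]) continue;   // niche width saturated
        if (rec.cellset.count(d)) continue;       // already part of range
        cand.push_back(d);
      }
    }
    if (cand.empty()) {
      log(clock_, EV_COLONIZE_BLOCKED, sp, rec.parent, src, -1);
      return;
    }
    int pick = (int)(unif_rand() * cand.size());
    if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
    int dst = cand[pick];
    if (local_adapt) {
      double dTT = tp - temp[dst];
      double w = std::exp(-(dTT * dTT) / (2.0 * V));
      if (unif_rand() > w) {
        log(clock_, EV_COLONIZE_REJECTED, sp, rec.parent, src, dst);
        return;
      }
    }
    double tp_child = tp + norm_rand();  // preference evolves on colonization
    add_population(sp, dst, tp_child);
    log(clock_, EV_COLONIZE, sp, rec.parent, src, dst);
  }

  void do_extirpation(int idx) {
    int sp = pop_sp[idx], cell = pop_cell[idx];
    int parent = species.at(sp).parent;
    bool extinct = remove_population(idx);
    log(clock_, EV_EXTIRPATE, sp, parent, cell, -1);
    if (extinct) log(clock_, EV_SPECIES_EXTINCT, sp, parent, cell, -1);
  }

  void do_speciation(int idx) {
    int old_sp = pop_sp[idx];
    int cell = pop_cell[idx];
    SpeciesRec& old_rec = species.at(old_sp);
    int b = band[cell];

    int new_sp = next_species++;
    SpeciesRec rec;
    rec.origin_band = b;
    rec.parent = old_sp;
    rec.cells.push_back(cell);
    rec.cellset.insert(cell);
    rec.bandcnt.assign(nbands, 0);
    rec.bandcnt[b] = 1;
    species.emplace(new_sp, std::move(rec));

    // parent loses the cell; the new species holds it, so occupancy and the
    // per-cell species count are unchanged
    for (size_t i = 0; i < old_rec.cells.size(); ++i) {
      if (old_rec.cells[i] == cell) {
        old_rec.cells[i] = old_rec.cells.back();
        old_rec.cells.pop_back();
        break;
      }
    }
    old_rec.cellset.erase(cell);
    bump_band(old_rec, b, -1);
    band_rich[b] += 1;  // the newborn species is resident in band b
    pop_sp[idx] = new_sp;

    bool anagenetic = old_rec.cells.empty();
    if (anagenetic) species.erase(old_sp);
    log(clock_, anagenetic ? EV_ANAGENESIS : EV_SPECIATE,
        new_sp, old_sp, cell, cell);
  }

  // returns: 0 = budget exhausted, 1 = clade extinct, 2 = hit max_time
  int run(long long max_new_events, double max_time) {
    long long done = 0;
    while (done < max_new_events) {
      if (species.empty()) return 1;
      double tot = total_rate();
      double dt = exp_rand() / tot;
      if (clock_ + dt > max_time) {
        samples_until(max_time);
        clock_ = max_time;
        return 2;
      }
      samples_until(clock_ + dt);
      clock_ += dt;

      // pick band ~ n_b * (gamma + mu + lambda_b), then population, then kind
      double u = unif_rand() * tot;
      int b = 0;
      for (; b < nbands; ++b) {
        double w = band_pops[b].size() * (gamma_ + mu + bandLam[b]);
        if (u < w) break;
        u -= w;
      }
      if (b == nbands) b = nbands - 1;  // guard against roundoff
      while (band_pops[b].empty()) --b;
      int pick = (int)(unif_rand() * band_pops[b].size());
      if (pick >= (int)band_pops[b].size())
        pick = (int)band_pops[b].size() - 1;
      int idx = band_pops[b][pick];

      double kk = unif_rand() * (gamma_ + mu + bandLam[b]);
      if (kk < gamma_)
        do_colonization(idx);
      else if (kk < gamma_ + mu)
        do_extirpation(idx);
      else
        do_speciation(idx);
      ++n_events;
      ++done;
    }
    return 0;
  }
};

static Sim* get_sim(SEXP xp) {
  Rcpp::XPtr<Sim> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".sim_create")]]
SEXP sim_create(IntegerVector band, NumericVector temp, IntegerVector adj_ptr,
                IntegerVector adj, NumericVector bandK, NumericVector bandLam,
                double gamma_, double mu, bool local_adapt, double V,
                int origin_band, double sample_dt, bool log_events) {
  Sim* s = new Sim();
  s->ncell = band.size();
  s->nbands = bandK.size();
  s->band.assign(band.begin(), band.end());
  s->temp.assign(temp.begin(), temp.end());
  s->adj_ptr.assign(adj_ptr.begin(), adj_ptr.end());
  s->adj.assign(adj.begin(), adj.end());
  s->bandK.assign(bandK.begin(), bandK.end());
  s->bandLam.assign(bandLam.begin(), bandLam.end());
  s->gamma_ = gamma_;
  s->mu = mu;
  s->local_adapt = local_adapt;
  s->V = V;
  s->sample_dt = sample_dt;
  s->log_events = log_events;
  s->occ.assign(s->ncell, 0);
  s->band_pops.assign(s->nbands, {});
  s->band_rich.assign(s->nbands, 0);
  s->ts_band.assign(s->nbands, {});
  s->ts_mismatch.assign(s->nbands, {});
  s->seen_stamp.assign(s->ncell, 0);

  // founder: uniform cell of the origin band, preference matching the cell
  std::vector<int> cells;
  for (int c = 0; c < s->ncell; ++c)
    if (s->band[c] == origin_band) cells.push_back(c);
  if (cells.empty()) stop("origin band has no cells");
  int pick = (int)(unif_rand() * cells.size());
  if (pick >= (int)cells.size()) pick = (int)cells.size() - 1;
  int cell = cells[pick];

  SpeciesRec rec;
  rec.origin_band = origin_band;
  rec.parent = 0;
  rec.bandcnt.assign(s->nbands, 0);
  int sp = s->next_species++;
  s->species.emplace(sp, std::move(rec));
  s->add_population(sp, cell, s->temp[cell]);
  s->log(0.0, EV_SPECIATE, sp, 0, cell, cell);

  Rcpp::XPtr<Sim> ptr(s, true);
  return ptr;
}

// [[Rcpp::export(name = ".sim_run")]]
int sim_run(SEXP xp, double max_new_events, double max_time) {
  return get_sim(xp)->run((long long)max_new_events, max_time);
}

// [[Rcpp::export(name = ".sim_total_rate")]]
double sim_total_rate(SEXP xp) { return get_sim(xp)->total_rate(); }

// [[Rcpp::export(name = ".sim_clock")]]
double sim_clock(SEXP xp) { return get_sim(xp)->clock_; }

// [[Rcpp::export(name = ".sim_state")]]
List sim_state(SEXP xp) {
  Sim* s = get_sim(xp);
  int np = (int)s->pop_sp.size();
  IntegerVector psp(np), pcell(np);
  NumericVector ptp(np);
  for (int i = 0; i < np; ++i) {
    psp[i] = s->pop_sp[i];
    pcell[i] = s->pop_cell[i] + 1;  // 1-based for R
    ptp[i] = s->pop_tp[i];
  }
  int ns = (int)s->species.size();
  IntegerVector sid(ns), sparent(ns), sorigin(ns), snpop(ns);
  int j = 0;
  for (const auto& kv : s->species) {
    sid[j] = kv.first;
    sparent[j] = kv.second.parent;
    sorigin[j] = kv.second.origin_band;
    snpop[j] = (int)kv.second.cells.size();
    ++j;
  }
  return List::create(
      _["time"] = s->clock_, _["n_events"] = (double)s->n_events,
      _["populations"] = DataFrame::create(
          _["species_id"] = psp, _["cell_id"] = pcell,
          _["temperature_preference"] = ptp),
      _["species"] = DataFrame::create(
          _["species_id"] = sid, _["parent_species_id"] = sparent,
          _["origin_band"] = sorigin, _["n_populations"] = snpop),
      _["occupancy"] = IntegerVector(s->occ.begin(), s->occ.end()),
      _["band_richness"] =
          IntegerVector(s->band_rich.begin(), s->band_rich.end()),
      _["regional_richness"] = (int)s->species.size());
}

// [[Rcpp::export(name = ".sim_series")]]
List sim_series(SEXP xp) {
  Sim* s = get_sim(xp);
  int n = (int)s->ts_time.size();
  IntegerMatrix bm(n, s->nbands);
  NumericMatrix mm(n, s->nbands);
  for (int b = 0; b < s->nbands; ++b)
    for (int i = 0; i < n; ++i) {
      bm(i, b) = s->ts_band[b][i];
      mm(i, b) = s->ts_mismatch[b][i];
    }
  return List::create(
      _["time"] = NumericVector(s->ts_time.begin(), s->ts_time.end()),
      _["regional_richness"] =
          IntegerVector(s->ts_reg.begin(), s->ts_reg.end()),
      _["band_richness"] = bm, _["band_mismatch"] = mm);
}

// [[Rcpp::export(name = ".sim_log")]]
DataFrame sim_log(SEXP xp) {
  Sim* s = get_sim(xp);
  int n = (int)s->ev_time.size();
  IntegerVector src(n), dst(n);
  for (int i = 0; i < n; ++i) {
    src[i] = s->ev_src[i] >= 0 ? s->ev_src[i] + 1 : NA_INTEGER;
    dst[i] = s->ev_dst[i] >= 0 ? s->ev_dst[i] + 1 : NA_INTEGER;
  }
  return DataFrame::create(
      _["time"] = NumericVector(s->ev_time.begin(), s->ev_time.end()),
      _["kind"] = IntegerVector(s->ev_kind.begin(), s->ev_kind.end()),
      _["species_id"] = IntegerVector(s->ev_sp.begin(), s->ev_sp.end()),
      _["parent_id"] = IntegerVector(s->ev_parent.begin(), s->ev_parent.end()),
      _["source_cell"] = src, _["target_cell"] = dst);
}

// Apply one event of a given kind to the population of (species, cell)
// without advancing the clock; low-level hook used to exercise the event
// semantics deterministically.
// [[Rcpp::export(name = ".sim_force")]]
int sim_force(SEXP xp, int kind, int species_id, int cell_id) {
  Sim* s = get_sim(xp);
  int cell = cell_id - 1;
  int idx = -1;
  for (size_t i = 0; i < s->pop_sp.size(); ++i)
    if (s->pop_sp[i] == species_id && s->pop_cell[i] == cell) {
      idx = (int)i;
      break;
    }
  if (idx < 0) stop("no population of species %d in cell %d",
                    species_id, cell_id);
  if (kind == 0)
    s->do_colonization(idx);
  else if (kind == 1)
    s->do_extirpation(idx);
  else if (kind == 2)
    s->do_speciation(idx);
  else
    stop("unknown event kind");
  s->n_events += 1;
  return (int)s->species.size();
}

// consistency check: recompute occupancy and per-band richness from the
// population table and compare with the incremental counters
// [[Rcpp::export(name = ".sim_check")]]
bool sim_check(SEXP xp) {
  Sim* s = get_sim(xp);
  std::vector<int> occ(s->ncell, 0);
  for (size_t i = 0; i < s->pop_sp.size(); ++i) occ[s->pop_cell[i]] += 1;
  if (occ != s->occ) return false;
  for (int c = 0; c < s->ncell; ++c)
    if (occ[c] > s->bandK[s->band[c]]) return false;
  std::vector<std::unordered_set<int>> br(s->nbands);
  for (size_t i = 0; i < s->pop_sp.size(); ++i)
    br[s->band[s->pop_cell[i]]].insert(s->pop_sp[i]);
  for (int b = 0; b < s->nbands; ++b)
    if ((int)br[b].size() != s->band_rich[b]) return false;
  // species bookkeeping
  std::unordered_map<int, int> npop;
  for (size_t i = 0; i < s->pop_sp.size(); ++i) npop[s->pop_sp[i]] += 1;
  if (npop.size() != s->species.size()) return false;
  for (const auto& kv : s->species) {
    auto it = npop.find(kv.first);
    if (it == npop.end() || it->second != (int)kv.second.cells.size())
      return false;
  }
  return true;
}
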