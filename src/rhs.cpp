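// Joint concentration + isotopomer ODE right-hand side.
//
// The R side (compile.R) lowers a network, its rate laws and its atom maps
// into flat index tables once per (network, condition); this file evaluates
// them. Rate-law templates are mirrored exactly in R (kinetics.R,
// evalRateLaw); tests assert parity between the two paths.
//
// State layout: y = [totals of non-constant metabolites,
//                    isotopomer blocks of reachable labelable non-constant
//                    metabolites (2^n entries each, bit k-1 <=> 13C at Ck)].

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

enum Tmpl { MASSACTION = 1, MICHAELIS = 2, MICHAELISREV = 3, HILL = 4,
            GLUCOKINASE = 5, EXCHANGE = 6, EXPRESSION = 7 };

struct LawC {
  int tmpl;
  std::string id;
  std::vector<int> subIdx, subCoef, prodIdx, prodCoef, inhIdx;
  std::vector<int> gkIdx;          // glucokinase: S, ATP, I, R
  std::vector<double> pars;        // packed per template contract
  RObject exprFun;                 // expression laws only
};

struct StoichEntry { int state; double coefScale; };

struct LabelSlot {
  int isoOff;                      // offset into y, -1 if fixed
  int nStates;
  bool fixed;
  std::vector<double> fixedFrac;   // fractions when fixed
  double scale;                    // ncell / vol of the slot's compartment
};

struct LabelOp {
  int rxn;                         // reaction index
  int dir;                         // 0: use forward rate, 1: reverse rate
  std::vector<LabelSlot> subs;
  std::vector<int> prodOff;        // iso offsets (-1: not simulated)
  std::vector<double> prodScale;
  int nCombos, nSubs, nProds;
  std::vector<int> comboSub;       // nCombos x nSubs (column-major per slot)
  std::vector<int> comboProd;      // nCombos x nProds
  std::vector<int> comboProdAlt;   // symmetric alternative mask or -1
};

struct KLModel {
  int nMet, nTot, yLen;
  std::vector<int> stateIdx;       // per metabolite, -1 if constant
  std::vector<double> constVals;   // per metabolite (used when constant)
  std::vector<LawC> laws;
  std::vector<std::vector<StoichEntry> > stoich;
  std::vector<LabelOp> ops;
  std::vector<std::string> stateNames;
  CharacterVector metIds;
  // workspace
  std::vector<double> conc, fwd, rev;
  std::vector<std::vector<double> > fracbuf;
};

static inline double clamp0(double x) { return x > 0.0 ? x : 0.0; }

static void evalLaw(KLModel &m, const LawC &L, double &f, double &r) {
  const std::vector<double> &c = m.conc;
  f = 0.0; r = 0.0;
  switch (L.tmpl) {
  case MASSACTION: {
    double pf = L.pars[0], pr = L.pars[1];
    for (size_t i = 0; i < L.subIdx.size(); ++i)
      pf *= std::pow(c[L.subIdx[i]], L.subCoef[i]);
    f = pf;
    if (pr > 0.0) {
      for (size_t i = 0; i < L.prodIdx.size(); ++i)
        pr *= std::pow(c[L.prodIdx[i]], L.prodCoef[i]);
      r = pr;
    }
    break;
  }
  case MICHAELIS: {
    double v = L.pars[0];
    size_t nS = L.subIdx.size();
    for (size_t i = 0; i < nS; ++i) {
      double s = c[L.subIdx[i]], Km = L.pars[1 + i];
      v *= std::pow(s / (Km + s), L.subCoef[i]);
    }
    double inh = 0.0;
    for (size_t i = 0; i < L.inhIdx.size(); ++i)
      inh += c[L.inhIdx[i]] / L.pars[1 + nS + i];
    f = v / (1.0 + inh);
    break;
  }
  case MICHAELISREV: {
    size_t nS = L.subIdx.size(), nP = L.prodIdx.size();
    double Vf = L.pars[0];
    double numS = 1.0, numP = 1.0, dS = 1.0, dP = 1.0;
    double KsProd = 1.0, KpProd = 1.0;
    for (size_t i = 0; i < nS; ++i) {
      double s = c[L.subIdx[i]] / L.pars[1 + i];
      numS *= std::pow(s, L.subCoef[i]);
      dS *= std::pow(1.0 + s, L.subCoef[i]);
      KsProd *= std::pow(L.pars[1 + i], L.subCoef[i]);
    }
    for (size_t i = 0; i < nP; ++i) {
      double p = c[L.prodIdx[i]] / L.pars[1 + nS + i];
      numP *= std::pow(p, L.prodCoef[i]);
      dP *= std::pow(1.0 + p, L.prodCoef[i]);
      KpProd *= std::pow(L.pars[1 + nS + i], L.prodCoef[i]);
    }
    double keqOrVr = L.pars[1 + nS + nP];
    bool useHaldane = L.pars[2 + nS + nP] > 0.5;
    double inh = 0.0;
    for (size_t i = 0; i < L.inhIdx.size(); ++i)
      inh += c[L.inhIdx[i]] / L.pars[3 + nS + nP + i];
    double D = dS + dP - 1.0 + inh;
    double Vr = useHaldane ? Vf * KpProd / (keqOrVr * KsProd) : keqOrVr;
    f = Vf * numS / D;
    r = Vr * numP / D;
    break;
  }
  case HILL: {
    double v = L.pars[0], K = L.pars[1], h = L.pars[2];
    double s1 = c[L.subIdx[0]];
    double sh = std::pow(s1, h);
    v *= sh / (std::pow(K, h) + sh);
    for (size_t i = 1; i < L.subIdx.size(); ++i) {
      double s = c[L.subIdx[i]], Km = L.pars[2 + i];
      v *= s / (Km + s);
    }
    f = v;
    break;
  }
  case GLUCOKINASE: {
    double s = c[L.gkIdx[0]], atp = c[L.gkIdx[1]];
    double inhC = c[L.gkIdx[2]], rel = c[L.gkIdx[3]];
    double Vmax = L.pars[0], Km = L.pars[1], KmATP = L.pars[2],
           Ki = L.pars[3], Kir = L.pars[4];
    double inh = (inhC / Ki) / (1.0 + rel / Kir);
    f = Vmax * s / (Km * (1.0 + inh) + s) * atp / (KmATP + atp);
    break;
  }
  case EXCHANGE: {
    double v = L.pars[0];
    for (size_t i = 0; i < L.subIdx.size(); ++i)
      v *= std::pow(c[L.subIdx[i]], L.subCoef[i]);
    for (size_t i = 0; i < L.prodIdx.size(); ++i)
      v *= std::pow(c[L.prodIdx[i]], L.prodCoef[i]);
    f = v; r = v;
    break;
  }
  case EXPRESSION: {
    NumericVector cv(m.conc.begin(), m.conc.end());
    cv.attr("names") = m.metIds;
    Function fn(L.exprFun);
    NumericVector res = fn(cv);
    f = res[0]; r = res[1];
    break;
  }
  default:
    stop("reaction '%s': unknown rate-law template id", L.id.c_str());
  }
  if (!std::isfinite(f) || !std::isfinite(r))
    stop("reaction '%s': non-finite rate (division by zero in the law?)",
         L.id.c_str());
}

static void fillConc(KLModel &m, const NumericVector &y) {
  for (int i = 0; i < m.nMet; ++i) {
    int s = m.stateIdx[i];
    m.conc[i] = (s < 0) ? m.constVals[i] : clamp0(y[s]);
  }
}

static void computeRates(KLModel &m, const NumericVector &y) {
  fillConc(m, y);
  for (size_t k = 0; k < m.laws.size(); ++k)
    evalLaw(m, m.laws[k], m.fwd[k], m.rev[k]);
}

// [[Rcpp::export]]
SEXP kl_model_build(List spec) {
  KLModel *m = new KLModel();
  m->nMet = as<int>(spec["nMet"]);
  m->nTot = as<int>(spec["nTot"]);
  m->yLen = as<int>(spec["yLen"]);
  m->stateIdx = as<std::vector<int> >(spec["stateIdx"]);
  m->constVals = as<std::vector<double> >(spec["constVals"]);
  m->stateNames = as<std::vector<std::string> >(spec["stateNames"]);
  m->metIds = as<CharacterVector>(spec["metIds"]);

  List laws = spec["laws"];
  for (int i = 0; i < laws.size(); ++i) {
    List l = laws[i];
    LawC L;
    L.tmpl = as<int>(l["tmpl"]);
    L.id = as<std::string>(l["id"]);
    L.subIdx = as<std::vector<int> >(l["subIdx"]);
    L.subCoef = as<std::vector<int> >(l["subCoef"]);
    L.prodIdx = as<std::vector<int> >(l["prodIdx"]);
    L.prodCoef = as<std::vector<int> >(l["prodCoef"]);
    L.inhIdx = as<std::vector<int> >(l["inhIdx"]);
    L.gkIdx = as<std::vector<int> >(l["gkIdx"]);
    L.pars = as<std::vector<double> >(l["pars"]);
    L.exprFun = as<RObject>(l["exprFun"]);
    m->laws.push_back(L);
  }

  List stoich = spec["stoich"];
  for (int i = 0; i < stoich.size(); ++i) {
    List s = stoich[i];
    std::vector<int> idx = as<std::vector<int> >(s["idx"]);
    std::vector<double> val = as<std::vector<double> >(s["val"]);
    std::vector<StoichEntry> es(idx.size());
    for (size_t k = 0; k < idx.size(); ++k) {
      es[k].state = idx[k]; es[k].coefScale = val[k];
    }
    m->stoich.push_back(es);
  }

  List ops = spec["labelOps"];
  for (int i = 0; i < ops.size(); ++i) {
    List o = ops[i];
    LabelOp op;
    op.rxn = as<int>(o["rxn"]);
    op.dir = as<int>(o["dir"]);
    List subs = o["subs"];
    for (int k = 0; k < subs.size(); ++k) {
      List s = subs[k];
      LabelSlot sl;
      sl.isoOff = as<int>(s["isoOff"]);
      sl.nStates = as<int>(s["nStates"]);
      sl.fixed = as<bool>(s["fixed"]);
      sl.fixedFrac = as<std::vector<double> >(s["fixedFrac"]);
      sl.scale = as<double>(s["scale"]);
      op.subs.push_back(sl);
    }
    op.prodOff = as<std::vector<int> >(o["prodOff"]);
    op.prodScale = as<std::vector<double> >(o["prodScale"]);
    op.comboSub = as<std::vector<int> >(o["comboSub"]);
    op.comboProd = as<std::vector<int> >(o["comboProd"]);
    op.comboProdAlt = as<std::vector<int> >(o["comboProdAlt"]);
    op.nSubs = (int)op.subs.size();
    op.nProds = (int)op.prodOff.size();
    op.nCombos = op.nSubs ? (int)(op.comboSub.size() / op.nSubs)
                          : (op.nProds ? (int)(op.comboProd.size() / op.nProds) : 1);
    m->ops.push_back(op);
  }

  m->conc.resize(m->nMet);
  m->fwd.resize(m->laws.size());
  m->rev.resize(m->laws.size());
  size_t maxStates = 2;
  for (size_t i = 0; i < m->ops.size(); ++i)
    for (size_t k = 0; k < m->ops[i].subs.size(); ++k)
      maxStates = std::max(maxStates, (size_t)m->ops[i].subs[k].nStates);
  m->fracbuf.assign(8, std::vector<double>(maxStates));

  XPtr<KLModel> p(m, true);
  return p;
}

// [[Rcpp::export]]
void kl_model_set_pars(SEXP ptr, List parsList) {
  XPtr<KLModel> m(ptr);
  if ((size_t)parsList.size() != m->laws.size())
    stop("parameter list length does not match the number of reactions");
  for (int i = 0; i < parsList.size(); ++i)
    m->laws[i].pars = as<std::vector<double> >(parsList[i]);
}

// [[Rcpp::export]]
void kl_model_set_const(SEXP ptr, NumericVector constVals) {
  XPtr<KLModel> m(ptr);
  if ((int)constVals.size() != m->nMet) stop("constVals length mismatch");
  m->constVals = as<std::vector<double> >(constVals);
}

// [[Rcpp::export]]
NumericMatrix kl_rates(SEXP ptr, NumericVector y) {
  XPtr<KLModel> m(ptr);
  computeRates(*m, y);
  NumericMatrix out(m->laws.size(), 2);
  for (size_t k = 0; k < m->laws.size(); ++k) {
    out(k, 0) = m->fwd[k]; out(k, 1) = m->rev[k];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector kl_rhs(SEXP ptr, double t, NumericVector y) {
  XPtr<KLModel> m(ptr);
  computeRates(*m, y);
  NumericVector dy(m->yLen);

  // totals: dc_i/dt = sum_r N_ir * (f_r - r_r) * ncell/vol_i
  for (size_t r = 0; r < m->stoich.size(); ++r) {
    double net = m->fwd[r] - m->rev[r];
    if (net == 0.0) continue;
    const std::vector<StoichEntry> &es = m->stoich[r];
    for (size_t k = 0; k < es.size(); ++k)
      dy[es[k].state] += es[k].coefScale * net;
  }

  // isotopomer fluxes
  for (size_t io = 0; io < m->ops.size(); ++io) {
    const LabelOp &op = m->ops[io];
    double J = (op.dir == 0) ? m->fwd[op.rxn] : m->rev[op.rxn];
    if (J <= 0.0) continue;

    // fractional abundances per labelable substrate slot
    for (int k = 0; k < op.nSubs; ++k) {
      const LabelSlot &sl = op.subs[k];
      std::vector<double> &fr = m->fracbuf[k];
      if (sl.fixed) {
        for (int s = 0; s < sl.nStates; ++s) fr[s] = sl.fixedFrac[s];
      } else {
        double tot = 0.0;
        for (int s = 0; s < sl.nStates; ++s) tot += clamp0(y[sl.isoOff + s]);
        if (tot < 1e-12) {                 // zero-pool guard: all unlabelled
          for (int s = 0; s < sl.nStates; ++s) fr[s] = 0.0;
          fr[0] = 1.0;
        } else {
          for (int s = 0; s < sl.nStates; ++s)
            fr[s] = clamp0(y[sl.isoOff + s]) / tot;
        }
      }
      // substrate depletion: -J * frac * ncell/vol
      if (!sl.fixed)
        for (int s = 0; s < sl.nStates; ++s)
          dy[sl.isoOff + s] -= J * sl.scale * fr[s];
    }

    // product accumulation over substrate isotopomer combinations
    for (int cb = 0; cb < op.nCombos; ++cb) {
      double w = J;
      for (int k = 0; k < op.nSubs; ++k)
        w *= m->fracbuf[k][op.comboSub[(size_t)cb * op.nSubs + k]];
      if (w == 0.0) continue;
      for (int p = 0; p < op.nProds; ++p) {
        int off = op.prodOff[p];
        if (off < 0) continue;
        size_t cell = (size_t)cb * op.nProds + p;
        int mask = op.comboProd[cell];
        int alt = op.comboProdAlt[cell];
        double wp = w * op.prodScale[p];
        if (alt >= 0) {                    // symmetric molecule: split 50/50
          dy[off + mask] += 0.5 * wp;
          dy[off + alt] += 0.5 * wp;
        } else {
          dy[off + mask] += wp;
        }
      }
    }
  }

  for (int i = 0; i < m->yLen; ++i)
    if (!std::isfinite(dy[i]))
      stop("non-finite derivative for state '%s'", m->stateNames[i].c_str());
  return dy;
}
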