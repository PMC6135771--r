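// Coarse-grained hairpin energy + Metropolis sweep kernel, and the zipper
// sampler segment.  Hot loops only; all bookkeeping stays in R.  Random
// numbers come from R's RNG so replica streams set via .Random.seed on the
// R side carry through deterministically.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3 &o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3 &o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3 &o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3 &o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

static inline bool unit(const Vec3 &v, Vec3 &out) {
  double n = v.norm();
  if (n < 1e-10) return false;
  out = v * (1.0 / n);
  return true;
}

static inline Vec3 anyPerp(const Vec3 &u) {
  Vec3 e = (std::fabs(u.z) < 0.9) ? Vec3(0, 0, 1) : Vec3(1, 0, 0);
  Vec3 p = e - u * e.dot(u), o;
  unit(p, o);
  return o;
}

// Mirrors the R-side surrogate-bead framing exactly (see frameFromCA).
static const double DELTA_HB = 1.9, GAMMA_T = 0.5, DELTA_SC = 2.0;

struct Params {
  double bondK, bondR0, angleK, dihedralK, evK, evSigma;
  double epsHb, hbOn, hbOff, hbCoop, epsSc, scOn, scOff;
  double lambdaLoop, qScale, debye;
  double hbCount, scCount;
  int loopLo, loopHi;           // 1-based residue range with scaled bonded terms
  std::vector<double> theta0;   // native CA angles, index = central residue-1
  std::vector<double> phi0;     // native loop dihedrals
  std::vector<int> dihStart;    // 1-based first residue of each loop dihedral
  std::vector<int> donorRes, acceptorRes;  // H-bond registry (residues)
  std::vector<int> zipOrder;               // registry order turn -> termini
  std::vector<int> scA, scB;               // sidechain pair residues
  std::vector<double> charge;              // per residue
};

static Params parseParams(const List &par) {
  Params p;
  p.bondK = as<double>(par["bondK"]);     p.bondR0 = as<double>(par["bondR0"]);
  p.angleK = as<double>(par["angleK"]);   p.dihedralK = as<double>(par["dihedralK"]);
  p.evK = as<double>(par["evK"]);         p.evSigma = as<double>(par["evSigma"]);
  p.epsHb = as<double>(par["epsHb"]);     p.hbOn = as<double>(par["hbOn"]);
  p.hbOff = as<double>(par["hbOff"]);     p.hbCoop = as<double>(par["hbCoop"]);
  p.epsSc = as<double>(par["epsSc"]);
  p.scOn = as<double>(par["scOn"]);       p.scOff = as<double>(par["scOff"]);
  p.lambdaLoop = as<double>(par["lambdaLoop"]);
  p.qScale = as<double>(par["qScale"]);   p.debye = as<double>(par["debye"]);
  p.hbCount = as<double>(par["hbCount"]); p.scCount = as<double>(par["scCount"]);
  p.loopLo = as<int>(par["loopLo"]);      p.loopHi = as<int>(par["loopHi"]);
  p.theta0 = as<std::vector<double> >(par["theta0"]);
  p.phi0 = as<std::vector<double> >(par["phi0"]);
  p.dihStart = as<std::vector<int> >(par["dihStart"]);
  p.zipOrder = as<std::vector<int> >(par["zipOrder"]);
  p.donorRes = as<std::vector<int> >(par["donorRes"]);
  p.acceptorRes = as<std::vector<int> >(par["acceptorRes"]);
  p.scA = as<std::vector<int> >(par["scA"]);
  p.scB = as<std::vector<int> >(par["scB"]);
  p.charge = as<std::vector<double> >(par["charge"]);
  return p;
}

// Framed O/HN/SC positions for interior residue i (0-based CA index).
static void frameRes(const std::vector<Vec3> &ca, int i,
                     Vec3 &O, Vec3 &HN, Vec3 &SC) {
  Vec3 u, v, b, t, n;
  if (!unit(ca[i + 1] - ca[i], u) || !unit(ca[i - 1] - ca[i], v))
    stop("coincident CA beads in framing");
  if (!unit(u + v, b)) b = anyPerp(u);
  if (!unit(ca[i + 1] - ca[i - 1], t)) t = u;
  if (!unit(u.cross(v), n)) unit(u.cross(b), n);
  O = ca[i] + b * DELTA_HB + t * GAMMA_T;
  HN = ca[i] + b * DELTA_HB - t * GAMMA_T;
  SC = ca[i] + n * DELTA_SC;
}

static inline double switchWell(double r, double on, double off) {
  if (r <= on) return 1.0;
  if (r >= off) return 0.0;
  return 0.5 * (1.0 + std::cos(M_PI * (r - on) / (off - on)));
}

struct EnergyOut {
  double bonded, ev, hb, sc, chg;
  int nhb, nsc;
  double total() const { return bonded + ev + hb + sc + chg; }
};

static EnergyOut cgEnergyImpl(const std::vector<Vec3> &ca, const Params &p) {
  int n = (int)ca.size();
  EnergyOut e; e.bonded = e.ev = e.hb = e.sc = e.chg = 0; e.nhb = e.nsc = 0;

  // bonds
  for (int i = 0; i + 1 < n; ++i) {
    double r = (ca[i + 1] - ca[i]).norm();
    e.bonded += p.bondK * (r - p.bondR0) * (r - p.bondR0);
  }
  // angles (central residue i, 1-based i+1 here)
  for (int i = 1; i + 1 < n; ++i) {
    Vec3 a, b;
    if (!unit(ca[i - 1] - ca[i], a) || !unit(ca[i + 1] - ca[i], b)) continue;
    double c = a.dot(b);
    if (c > 1) c = 1; if (c < -1) c = -1;
    double th = std::acos(c);
    int res = i + 1;
    double lam = (res >= p.loopLo && res <= p.loopHi) ? p.lambdaLoop : 1.0;
    double d = th - p.theta0[i];
    e.bonded += p.angleK * lam * d * d;
  }
  // loop dihedrals
  for (size_t k = 0; k < p.dihStart.size(); ++k) {
    int i = p.dihStart[k] - 1;  // 0-based first CA
    Vec3 b1 = ca[i + 1] - ca[i], b2 = ca[i + 2] - ca[i + 1],
         b3 = ca[i + 3] - ca[i + 2];
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double n2norm = b2.norm();
    double x = n1.dot(n2), y = b2.norm() > 0 ? (b1.dot(n2)) * n2norm : 0;
    double phi = std::atan2(y, x);
    e.bonded += p.dihedralK * p.lambdaLoop * (1.0 - std::cos(phi - p.phi0[k]));
  }
  // excluded volume (CA pairs |i-j| >= 3); finite at r = 0
  for (int i = 0; i < n; ++i)
    for (int j = i + 3; j < n; ++j) {
      double r = (ca[j] - ca[i]).norm();
      if (r < p.evSigma) e.ev += p.evK * (p.evSigma - r) * (p.evSigma - r);
    }
  // frames for residues referenced by contacts
  std::vector<Vec3> O(n), HN(n), SC(n);
  std::vector<bool> framed(n, false);
  for (int i = 1; i + 1 < n; ++i) {
    frameRes(ca, i, O[i], HN[i], SC[i]);
    framed[i] = true;
  }
  // native H-bond wells, plus a nearest-neighbour cooperative bonus on
  // consecutively formed bonds in zipper order (turn outward): contiguous
  // zipped stretches are rewarded beyond the per-bond well depth.
  std::vector<double> sWell(p.donorRes.size(), 0.0);
  for (size_t k = 0; k < p.donorRes.size(); ++k) {
    int d = p.donorRes[k] - 1, a = p.acceptorRes[k] - 1;
    if (!framed[d] || !framed[a]) stop("registry references unframed residue");
    double r = (HN[d] - O[a]).norm();
    sWell[k] = switchWell(r, p.hbOn, p.hbOff);
    e.hb -= p.epsHb * sWell[k];
    if (r <= p.hbCount) e.nhb++;
  }
  if (p.hbCoop != 0.0 && p.zipOrder.size() >= 2)
    for (size_t k = 0; k + 1 < p.zipOrder.size(); ++k)
      e.hb -= p.hbCoop * sWell[p.zipOrder[k] - 1] *
              sWell[p.zipOrder[k + 1] - 1];
  // native sidechain wells
  for (size_t k = 0; k < p.scA.size(); ++k) {
    int ia = p.scA[k] - 1, ib = p.scB[k] - 1;
    double r = (SC[ia] - SC[ib]).norm();
    e.sc -= p.epsSc * switchWell(r, p.scOn, p.scOff);
    if (r <= p.scCount) e.nsc++;
  }
  // screened charges
  if (p.qScale != 0.0) {
    for (int i = 0; i < n; ++i) {
      if (p.charge[i] == 0) continue;
      for (int j = i + 2; j < n; ++j) {
        if (p.charge[j] == 0) continue;
        double r = (ca[j] - ca[i]).norm();
        if (r < 0.5) r = 0.5;  // finite at overlap
        e.chg += p.qScale * p.charge[i] * p.charge[j] *
                 std::exp(-r / p.debye) / r;
      }
    }
  }
  return e;
}

static std::vector<Vec3> toVec(const NumericMatrix &m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return v;
}

// [[Rcpp::export(name = ".cg_energy_cpp")]]
NumericVector cg_energy_cpp(NumericMatrix ca, List par) {
  Params p = parseParams(par);
  std::vector<Vec3> v = toVec(ca);
  EnergyOut e = cgEnergyImpl(v, p);
  NumericVector out = NumericVector::create(
    _["bonded"] = e.bonded, _["excluded_volume"] = e.ev,
    _["hbond_contact"] = e.hb, _["sidechain_contact"] = e.sc,
    _["screened_charge"] = e.chg);
  out.attr("nhb") = e.nhb;
  out.attr("nsc") = e.nsc;
  return out;
}

static inline Vec3 rotate(const Vec3 &v, const Vec3 &axis, double ang) {
  // Rodrigues rotation; axis must be unit length
  double c = std::cos(ang), s = std::sin(ang);
  return v * c + axis.cross(v) * s + axis * (axis.dot(v) * (1 - c));
}

static Vec3 randomAxis() {
  // Marsaglia rejection on the unit sphere
  for (;;) {
    double a = 2 * unif_rand() - 1, b = 2 * unif_rand() - 1;
    double s = a * a + b * b;
    if (s < 1) {
      double f = 2 * std::sqrt(1 - s);
      return Vec3(a * f, b * f, 1 - 2 * s);
    }
  }
}

// One replica segment: nSweeps sweeps of n single-bead/crankshaft/pivot
// moves with full-energy Metropolis at inverse temperature beta.  Records
// per-sweep observables.  Proposal distribution is symmetric by
// construction (uniform displacements/angles, side and axis chosen
// independently of the configuration).
// [[Rcpp::export(name = ".cg_segment_cpp")]]
List cg_segment_cpp(NumericMatrix caIn, double beta, int nSweeps,
                    NumericVector moveWeights, NumericVector amps, List par) {
  Params p = parseParams(par);
  std::vector<Vec3> ca = toVec(caIn);
  int n = (int)ca.size();
  double w1 = moveWeights[0], w2 = w1 + moveWeights[1];
  double wTot = w2 + moveWeights[2];
  double ampLoc = amps[0], ampCrank = amps[1], ampPivot = amps[2];

  EnergyOut cur = cgEnergyImpl(ca, p);
  NumericMatrix rec(nSweeps, 10);
  int nAccept = 0, nProp = 0;
  std::vector<Vec3> trial(n);

  for (int sw = 0; sw < nSweeps; ++sw) {
    for (int mv = 0; mv < n; ++mv) {
      trial = ca;
      double u = unif_rand() * wTot;
      if (u < w1) {                       // local displacement
        int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
        trial[i] = trial[i] + Vec3((2 * unif_rand() - 1) * ampLoc,
                                   (2 * unif_rand() - 1) * ampLoc,
                                   (2 * unif_rand() - 1) * ampLoc);
      } else if (u < w2 && n >= 3) {      // crankshaft of one interior bead
        int i = (int)(unif_rand() * (n - 2)); if (i >= n - 2) i = n - 3;
        Vec3 ax;
        if (unit(trial[i + 2] - trial[i], ax)) {
          double ang = (2 * unif_rand() - 1) * ampCrank;
          trial[i + 1] = trial[i] + rotate(trial[i + 1] - trial[i], ax, ang);
        }
      } else {                            // pivot
        int piv = 1 + (int)(unif_rand() * (n - 2)); if (piv >= n - 1) piv = n - 2;
        bool cSide = unif_rand() < 0.5;
        Vec3 ax = randomAxis();
        double ang = (2 * unif_rand() - 1) * ampPivot;
        if (cSide)
          for (int j = piv + 1; j < n; ++j)
            trial[j] = trial[piv] + rotate(trial[j] - trial[piv], ax, ang);
        else
          for (int j = 0; j < piv; ++j)
            trial[j] = trial[piv] + rotate(trial[j] - trial[piv], ax, ang);
      }
      EnergyOut prop = cgEnergyImpl(trial, p);
      double dE = prop.total() - cur.total();
      ++nProp;
      if (dE <= 0 || unif_rand() < std::exp(-beta * dE)) {
        ca = trial;
        cur = prop;
        ++nAccept;
      }
    }
    // per-sweep record (recount distances for observables)
    std::vector<Vec3> cav = ca;
    rec(sw, 0) = cur.nhb;
    rec(sw, 1) = cur.nsc;
    rec(sw, 2) = (ca[5] - ca[10]).norm();        // CA6 - CA11
    rec(sw, 3) = (ca[0] - ca[n - 1]).norm();     // termini
    rec(sw, 4) = cur.bonded;
    rec(sw, 5) = cur.ev;
    rec(sw, 6) = cur.hb;
    rec(sw, 7) = cur.sc;
    rec(sw, 8) = cur.chg;
    rec(sw, 9) = cur.total();
  }
  NumericMatrix caOut(n, 3);
  for (int i = 0; i < n; ++i) {
    caOut(i, 0) = ca[i].x; caOut(i, 1) = ca[i].y; caOut(i, 2) = ca[i].z;
  }
  colnames(rec) = CharacterVector::create(
    "nhb", "nsc", "loop", "e2e", "bonded", "excluded_volume",
    "hbond_contact", "sidechain_contact", "screened_charge", "total");
  return List::create(_["ca"] = caOut, _["records"] = rec,
                      _["energy"] = cur.total(),
                      _["nAccept"] = nAccept, _["nProposed"] = nProp);
}

// Zipper segment: random walk on the support of Omega (levels with
// Omega > 0), proposing +-1 within that ordered support (reflecting at the
// ends by proposal rejection) and accepting by Metropolis on the level
// energies -N*epsilon and the degeneracy ratio.
// [[Rcpp::export(name = ".zipper_segment_cpp")]]
List zipper_segment_cpp(int n0, double beta, double eps,
                        NumericVector omega, int nSweeps) {
  std::vector<int> support;
  for (int i = 0; i < omega.size(); ++i)
    if (omega[i] > 0) support.push_back(i);
  int m = (int)support.size();
  int pos = -1;
  for (int k = 0; k < m; ++k) if (support[k] == n0) pos = k;
  if (pos < 0) stop("initial state has zero degeneracy");

  IntegerVector rec(nSweeps);
  for (int sw = 0; sw < nSweeps; ++sw) {
    int prop = pos + (unif_rand() < 0.5 ? -1 : 1);
    if (prop >= 0 && prop < m) {
      int Nc = support[pos], Np = support[prop];
      double dE = -(double)(Np - Nc) * eps;
      double logA = -beta * dE + std::log(omega[Np] / omega[Nc]);
      if (logA >= 0 || unif_rand() < std::exp(logA)) pos = prop;
    }
    rec[sw] = support[pos];
  }
  return List::create(_["N"] = support[pos], _["records"] = rec);
}
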