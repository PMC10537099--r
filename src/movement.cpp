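#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Behaviour codes. APPROACH (moving to / queueing at a feeder) is part of the
// eating behaviour for the time budget.
enum Behaviour { REST = 0, WALK = 1, EAT = 2, APPROACH = 3, NONE = 4 };

// Dedicated xorshift128+ stream for the interaction Bernoulli draws, so that
// changing movement parameters never perturbs the interaction sampling
// sequence (and vice versa: movement uses R's RNG).
struct XorShift {
  uint64_t s0, s1;
  explicit XorShift(uint64_t seed) {
    // splitmix64 initialisation
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    for (int k = 0; k < 2; ++k) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      t = t ^ (t >> 31);
      if (k == 0) s0 = t; else s1 = t;
    }
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  double unif() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = s1 + y;
    return (r >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline double clamp01(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".simulatePenCpp")]]
List simulate_pen_cpp(NumericVector pAlpha, NumericVector pBeta,
                      NumericMatrix delta, double threshold,
                      double stepLength, double penSide, int nFeeders,
                      double sensingRange, int targetInteractions,
                      int nStepsFixed, int maxSteps,
                      IntegerVector snapshotAt, bool logRecords,
                      int logTrajSteps, double interactionSeed) {
  const int n = pAlpha.size();
  if (pBeta.size() != n) stop("tendency vectors differ in length");
  const double r2 = sensingRange * sensingRange;

  // per-ordered-pair interaction probabilities (constant over time)
  std::vector<double> prob((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      prob[(size_t)i * n + j] = 1.0 / (1.0 + std::exp(-(pAlpha[i] + pBeta[j])));

  // feeders evenly spaced on the two opposite sides y = 0 and y = penSide
  std::vector<double> fx(nFeeders), fy(nFeeders);
  {
    int top = nFeeders / 2, bottom = nFeeders - top;
    for (int k = 0; k < bottom; ++k) {
      fx[k] = (k + 0.5) * penSide / bottom;
      fy[k] = 0.0;
    }
    for (int k = 0; k < top; ++k) {
      fx[bottom + k] = (k + 0.5) * penSide / top;
      fy[bottom + k] = penSide;
    }
  }
  std::vector<int> feederBy(nFeeders, -1); // occupying agent or -1

  // agent state; initial motivations ~ U(0, T), positions uniform in the pen
  std::vector<double> x(n), y(n), mE(n), mW(n), mR(n), heading(n, 0.0);
  std::vector<int> behav(n, NONE), target(n, -1), eatingAt(n, -1);
  for (int i = 0; i < n; ++i) {
    x[i] = unif_rand() * penSide;
    y[i] = unif_rand() * penSide;
    mE[i] = unif_rand() * threshold;
    mW[i] = unif_rand() * threshold;
    mR[i] = unif_rand() * threshold;
  }

  XorShift irng((uint64_t)interactionSeed);

  IntegerMatrix N(n, n), Y(n, n);
  long totalInteractions = 0, totalEncounters = 0;
  long budgetEat = 0, budgetWalk = 0, budgetRest = 0;
  std::vector<int> mealAgent, mealStep;
  std::vector<double> recStep, recPerf, recRecv, recPx, recPy, recRx, recRy;
  std::vector<double> trajStep, trajAgent, trajX, trajY, trajB;
  List snapshots(snapshotAt.size());
  int snapIdx = 0;
  bool reachedTarget = (targetInteractions <= 0);

  int step = 0;
  const int limit = nStepsFixed > 0 ? nStepsFixed : maxSteps;
  while (step < limit) {
    ++step;
    for (int i = 0; i < n; ++i) {
      // 1. motivation update from the behaviour expressed in the previous
      //    step (no change while approaching/queueing at a feeder)
      int expressed = behav[i];
      int col = -1;
      if (expressed == EAT) col = 0;
      else if (expressed == WALK) col = 1;
      else if (expressed == REST) col = 2;
      if (col >= 0) {
        mE[i] += delta(0, col);
        mW[i] += delta(1, col);
        mR[i] += delta(2, col);
        if (mE[i] < 0) mE[i] = 0;
        if (mW[i] < 0) mW[i] = 0;
        if (mR[i] < 0) mR[i] = 0;
      }

      // 2. behaviour decision: continue while the current behaviour's
      //    motivation is still above zero, otherwise start the
      //    highest-priority behaviour at/above threshold (eat > rest > walk),
      //    defaulting to rest
      bool cont = false;
      if (behav[i] == APPROACH) cont = true;               // until at feeder
      else if (behav[i] == EAT) cont = mE[i] > 0;
      else if (behav[i] == WALK) cont = mW[i] > 0;
      else if (behav[i] == REST) cont = mR[i] > 0;
      if (!cont) {
        if (behav[i] == EAT && eatingAt[i] >= 0) {          // meal finished
          feederBy[eatingAt[i]] = -1;
          eatingAt[i] = -1;
        }
        if (mE[i] >= threshold) {
          behav[i] = APPROACH;
          // target the nearest unoccupied feeder (nearest overall if all busy)
          int best = -1, bestFree = -1;
          double bd = 1e300, bdf = 1e300;
          for (int f = 0; f < nFeeders; ++f) {
            double dx = fx[f] - x[i], dy = fy[f] - y[i];
            double dd = dx * dx + dy * dy;
            if (dd < bd) { bd = dd; best = f; }
            if (feederBy[f] < 0 && dd < bdf) { bdf = dd; bestFree = f; }
          }
          target[i] = bestFree >= 0 ? bestFree : best;
        } else if (mR[i] >= threshold) {
          behav[i] = REST;
        } else if (mW[i] >= threshold) {
          behav[i] = WALK;
          heading[i] = unif_rand() * 2.0 * M_PI;
        } else {
          behav[i] = REST; // default behaviour; terminates immediately
        }
      }

      // 3. movement
      if (behav[i] == WALK) {
        double nx = x[i] + stepLength * std::cos(heading[i]);
        double ny = y[i] + stepLength * std::sin(heading[i]);
        if (nx < 0) { nx = -nx; heading[i] = M_PI - heading[i]; }
        if (nx > penSide) { nx = 2 * penSide - nx; heading[i] = M_PI - heading[i]; }
        if (ny < 0) { ny = -ny; heading[i] = -heading[i]; }
        if (ny > penSide) { ny = 2 * penSide - ny; heading[i] = -heading[i]; }
        x[i] = clamp01(nx, 0, penSide);
        y[i] = clamp01(ny, 0, penSide);
      } else if (behav[i] == APPROACH) {
        int f = target[i];
        if (f >= 0 && feederBy[f] >= 0 && feederBy[f] != i) {
          // target got taken: re-aim at the nearest free feeder if any
          int bestFree = -1; double bdf = 1e300;
          for (int g = 0; g < nFeeders; ++g) {
            if (feederBy[g] < 0) {
              double dx = fx[g] - x[i], dy = fy[g] - y[i];
              double dd = dx * dx + dy * dy;
              if (dd < bdf) { bdf = dd; bestFree = g; }
            }
          }
          if (bestFree >= 0) { target[i] = bestFree; f = bestFree; }
        }
        double dx = fx[f] - x[i], dy = fy[f] - y[i];
        double dist = std::sqrt(dx * dx + dy * dy);
        if (dist <= stepLength) {
          x[i] = fx[f]; y[i] = fy[f];
          if (feederBy[f] < 0) {               // claim and start the meal
            feederBy[f] = i;
            eatingAt[i] = f;
            behav[i] = EAT;
            mealAgent.push_back(i + 1);
            mealStep.push_back(step);
          }                                     // else queue in place
        } else {
          x[i] += stepLength * dx / dist;
          y[i] += stepLength * dy / dist;
        }
      }

      if (behav[i] == EAT || behav[i] == APPROACH) ++budgetEat;
      else if (behav[i] == WALK) ++budgetWalk;
      else ++budgetRest;

      if (logTrajSteps > 0 && step <= logTrajSteps) {
        trajStep.push_back(step);
        trajAgent.push_back(i + 1);
        trajX.push_back(x[i]);
        trajY.push_back(y[i]);
        trajB.push_back(behav[i]);
      }
    }

    // 4. encounters and directed interaction sampling: every pair within the
    //    sensing range is a potential interaction in both ordered directions
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy < r2) {
          N(i, j) += 1;
          N(j, i) += 1;
          totalEncounters += 2;
          if (irng.unif() < prob[(size_t)i * n + j]) {
            Y(i, j) += 1;
            ++totalInteractions;
            if (logRecords) {
              recStep.push_back(step); recPerf.push_back(i + 1);
              recRecv.push_back(j + 1); recPx.push_back(x[i]);
              recPy.push_back(y[i]); recRx.push_back(x[j]);
              recRy.push_back(y[j]);
            }
          }
          if (irng.unif() < prob[(size_t)j * n + i]) {
            Y(j, i) += 1;
            ++totalInteractions;
            if (logRecords) {
              recStep.push_back(step); recPerf.push_back(j + 1);
              recRecv.push_back(i + 1); recPx.push_back(x[j]);
              recPy.push_back(y[j]); recRx.push_back(x[i]);
              recRy.push_back(y[i]);
            }
          }
        }
      }
    }

    while (snapIdx < snapshotAt.size() &&
           totalInteractions >= snapshotAt[snapIdx]) {
      snapshots[snapIdx] = List::create(
        _["N"] = clone(N), _["y"] = clone(Y), _["step"] = step,
        _["totalInteractions"] = (double)totalInteractions);
      ++snapIdx;
    }

    if (nStepsFixed <= 0 && targetInteractions > 0 &&
        totalInteractions >= targetInteractions &&
        snapIdx >= snapshotAt.size()) {
      reachedTarget = true;
      break;
    }
  }
  if (nStepsFixed > 0 || targetInteractions <= 0) reachedTarget = true;

  NumericMatrix rec(recStep.size(), 7);
  if (logRecords && recStep.size() > 0) {
    for (size_t k = 0; k < recStep.size(); ++k) {
      rec(k, 0) = recStep[k]; rec(k, 1) = recPerf[k]; rec(k, 2) = recRecv[k];
      rec(k, 3) = recPx[k]; rec(k, 4) = recPy[k];
      rec(k, 5) = recRx[k]; rec(k, 6) = recRy[k];
    }
  }
  NumericMatrix traj(trajStep.size(), 5);
  for (size_t k = 0; k < trajStep.size(); ++k) {
    traj(k, 0) = trajStep[k]; traj(k, 1) = trajAgent[k];
    traj(k, 2) = trajX[k]; traj(k, 3) = trajY[k]; traj(k, 4) = trajB[k];
  }

  return List::create(
    _["N"] = N, _["y"] = Y, _["steps"] = step,
    _["totalInteractions"] = (double)totalInteractions,
    _["totalEncounters"] = (double)totalEncounters,
    _["mealAgent"] = wrap(mealAgent), _["mealStep"] = wrap(mealStep),
    _["budget"] = NumericVector::create(
      _["eat"] = (double)budgetEat, _["walk"] = (double)budgetWalk,
      _["rest"] = (double)budgetRest),
    _["records"] = rec, _["trajectory"] = traj,
    _["snapshots"] = snapshots, _["reachedTarget"] = reachedTarget);
}
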