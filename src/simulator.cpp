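#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Frame-stepped trial loop, mirroring the R reference semantics exactly,
// including the order of RNG draws (one unif per control frame for the
// greedy policy's lapse gate, then one normal draw when a key is down and
// input noise is active). Uses R's RNG so seeds reproduce across paths.

static const double SHIP = 36.0;
static const double FALL = 6.0;
static const double KEY_STEP = 6.0;
static const double DRIFT = 3.0;
static const double SPAN = 270.0;
static const int ENTRY_FRAMES = 45;

// section types: 0 off, 1 normal, 2 invisible, 3 fake (force acts for 1, 2)

// greedy gap plan on obstacles sorted by y; returns 0 none, 1 left, 2 right.
// Mirrors greedy_gap_plan() in R exactly: nearest reachable gap when the
// current column is blocked, wall-margin easing when clear.
static int plan_key(double x, double y,
                    const std::vector<double>& ox_by_y,
                    const std::vector<double>& oy_sorted,
                    double width, double lookahead, double push) {
  const double WALL_MARGIN = 45.0;
  // obstacles with oy + 36 > y and oy <= y + lookahead
  size_t lo_i = std::upper_bound(oy_sorted.begin(), oy_sorted.end(), y - SHIP) -
                oy_sorted.begin();
  size_t hi_i = std::upper_bound(oy_sorted.begin(), oy_sorted.end(), y + lookahead) -
                oy_sorted.begin();
  std::vector<double> gaps_lo, gaps_hi;
  if (lo_i < hi_i) {
    std::vector<std::pair<double, double> > blocked;
    blocked.reserve(hi_i - lo_i);
    for (size_t i = lo_i; i < hi_i; ++i) {
      double bl = std::max(0.0, ox_by_y[i] - (SHIP - 1));
      double bh = std::min(width - SHIP, ox_by_y[i] + (SHIP - 1));
      blocked.push_back(std::make_pair(bl, bh));
    }
    std::sort(blocked.begin(), blocked.end());
    double cursor = 0.0;
    for (size_t i = 0; i < blocked.size(); ++i) {
      if (blocked[i].first > cursor) {
        gaps_lo.push_back(cursor);
        gaps_hi.push_back(blocked[i].first - 1);
      }
      cursor = std::max(cursor, blocked[i].second + 1);
    }
    if (cursor <= width - SHIP) {
      gaps_lo.push_back(cursor);
      gaps_hi.push_back(width - SHIP);
    }
  } else {
    gaps_lo.push_back(0.0);
    gaps_hi.push_back(width - SHIP);
  }
  if (gaps_lo.empty()) return 0;
  // gaps narrower than MIN_GAP cannot be held with 6-px quantized steps
  const double MIN_GAP = 18.0;
  for (size_t g = 0; g < gaps_lo.size(); ++g) {
    if (x >= gaps_lo[g] && x <= gaps_hi[g] &&
        gaps_hi[g] - gaps_lo[g] >= MIN_GAP) {
      if (x < WALL_MARGIN && gaps_hi[g] > x) return 2;
      if (x > width - SHIP - WALL_MARGIN && gaps_lo[g] < x) return 1;
      // active steering toward the gap center (exposes the trajectory to
      // input noise on most frames, like continuous micro-adjustment)
      double center = (gaps_lo[g] + gaps_hi[g]) / 2.0;
      if (x < center - 12) return 2;
      if (x > center + 12) return 1;
      return 0;
    }
  }
  const double MARGIN_FRAMES = 3.0;
  double best_dist = R_PosInf;
  int best_g = -1;
  double best_w = -1;
  int widest_g = 0;
  for (size_t g = 0; g < gaps_lo.size(); ++g) {
    double target = std::min(std::max(x, gaps_lo[g] + 6), gaps_hi[g] - 6);
    double dist = std::fabs(target - x);
    // transit safety vs every obstacle column crossed on the way; the
    // lateral speed accounts for the currently felt drift push
    bool safe = gaps_hi[g] - gaps_lo[g] >= MIN_GAP;
    if (!safe) {
      if (gaps_hi[g] - gaps_lo[g] > best_w) {
        best_w = gaps_hi[g] - gaps_lo[g];
        widest_g = (int)g;
      }
      continue;
    }
    double dir = (target >= x) ? 1.0 : -1.0;
    double speed = KEY_STEP + push * dir;
    double span_lo = std::min(x, target) - (SHIP - 1);
    double span_hi = std::max(x, target) + (SHIP - 1);
    for (size_t i = lo_i; i < hi_i; ++i) {
      if (ox_by_y[i] < span_lo || ox_by_y[i] > span_hi) continue;
      double dxo = std::fabs(ox_by_y[i] - x);
      double t1 = (dxo - SHIP) / speed;
      double t2 = (dxo + SHIP) / speed;
      double a1 = (oy_sorted[i] - SHIP - y) / FALL;
      double a2 = (oy_sorted[i] + SHIP - y) / FALL;
      if (t1 < a2 + MARGIN_FRAMES && t2 > a1 - MARGIN_FRAMES) { safe = false; break; }
    }
    double width_g = gaps_hi[g] - gaps_lo[g];
    if (safe && (dist < best_dist - 1e-9 ||
                 (std::fabs(dist - best_dist) <= 1e-9 && best_g >= 0 &&
                  width_g > gaps_hi[best_g] - gaps_lo[best_g]))) {
      best_dist = dist;
      best_g = (int)g;
    }
    if (gaps_hi[g] - gaps_lo[g] > best_w) {
      best_w = gaps_hi[g] - gaps_lo[g];
      widest_g = (int)g;
    }
  }
  int g = (best_g >= 0) ? best_g : widest_g;
  double near_pt = std::min(std::max(x, gaps_lo[g] + 6), gaps_hi[g] - 6);
  double target = (near_pt + (gaps_lo[g] + gaps_hi[g]) / 2.0) / 2.0;
  if (std::fabs(target - x) < 1e-9) return 0;
  return (target > x) ? 2 : 1;
}

// [[Rcpp::export]]
List cpp_run_trial(NumericVector obs_x, NumericVector obs_y,
                   NumericVector drift_y, IntegerVector drift_type,
                   IntegerVector drift_right,
                   int length_px, int width_px,
                   double noise_sd, bool drift_enabled,
                   double manipulation_from_y,
                   bool greedy, double lookahead, double skill,
                   int lag) {
  int n_obs = obs_x.size();
  int n_dr = drift_y.size();

  // obstacles sorted by y for lookahead / visibility queries
  std::vector<int> ord(n_obs);
  for (int i = 0; i < n_obs; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return obs_y[a] < obs_y[b]; });
  std::vector<double> oy_sorted(n_obs), ox_by_y(n_obs);
  for (int i = 0; i < n_obs; ++i) {
    oy_sorted[i] = obs_y[ord[i]];
    ox_by_y[i] = obs_x[ord[i]];
  }

  int max_frames = ENTRY_FRAMES + length_px / (int)FALL + 10;
  IntegerVector frame(max_frames), key_out(max_frames), nob(max_frames),
      ndr(max_frames);
  NumericVector xs(max_frames), ys(max_frames), dxs(max_frames);
  LogicalVector drift_act(max_frames), control(max_frames);

  double x = (width_px - SHIP) / 2.0;
  double y = -ENTRY_FRAMES * FALL;
  std::vector<int> queue(std::max(lag, 0), 0);
  int qpos = 0;
  bool completed = true;
  int crash_frame = NA_INTEGER;
  int i = 0;

  while (y < length_px && i < max_frames) {
    bool is_entry = (y + FALL) <= 0.0;
    int key = 0;
    if (!is_entry) {
      int planned = 0;
      if (greedy) {
        bool lapse = unif_rand() > skill;
        // plan from the state predicted once the queued keys land, so the
        // reaction lag does not cause systematic overshoot
        double x_pred = x, y_pred = y;
        if (lag > 0) {
          int sumdir = 0;
          for (int q = 0; q < lag; ++q) {
            if (queue[q] == 2) ++sumdir;
            else if (queue[q] == 1) --sumdir;
          }
          // drift accumulated while the queued keys land
          double queued_drift = 0.0;
          if (drift_enabled) {
            for (int q = 1; q <= lag; ++q) {
              double yq = y + FALL * q;
              if (yq < manipulation_from_y) continue;
              for (int k = 0; k < n_dr; ++k) {
                if (yq >= drift_y[k] && yq < drift_y[k] + SPAN) {
                  int tt = drift_type[k];
                  if (tt == 1 || tt == 2)
                    queued_drift += drift_right[k] ? DRIFT : -DRIFT;
                  break;
                }
              }
            }
          }
          x_pred += KEY_STEP * sumdir + queued_drift;
          y_pred += FALL * lag;
        }
        // drift push the ship will feel once the queued keys land
        double y_feel = y_pred + FALL;
        double push = 0.0;
        if (drift_enabled && y_feel >= manipulation_from_y) {
          for (int k = 0; k < n_dr; ++k) {
            if (y_feel >= drift_y[k] && y_feel < drift_y[k] + SPAN) {
              int tt = drift_type[k];
              if (tt == 1 || tt == 2) push = drift_right[k] ? DRIFT : -DRIFT;
              break;
            }
          }
        }
        planned = plan_key(x_pred, y_pred, ox_by_y, oy_sorted, width_px,
                           lookahead, push);
        if (planned == 0) {
          // station-hold against felt drift: counter-tap every other frame
          // (one 6-px key per two frames cancels the 3-px/frame push)
          long frame_pred = (long)i + lag;
          if (push != 0.0 && frame_pred % 2 == 0) planned = (push > 0) ? 1 : 2;
        }
        if (lapse) planned = 0;
      }
      if (lag > 0) {
        key = queue[qpos];
        queue[qpos] = planned;
        qpos = (qpos + 1) % lag;
      } else {
        key = planned;
      }
    }
    // step
    double y2 = y + FALL;
    double dx = 0.0;
    if (key != 0) {
      double sd = (y2 < manipulation_from_y) ? 0.0 : noise_sd;
      double delta = (sd > 0) ? (KEY_STEP + sd * norm_rand()) : KEY_STEP;
      dx += (key == 2) ? delta : -delta;
    }
    bool pushed = false;
    if (drift_enabled && y2 >= manipulation_from_y) {
      for (int k = 0; k < n_dr; ++k) {
        if (y2 >= drift_y[k] && y2 < drift_y[k] + SPAN) {
          int t = drift_type[k];
          if (t == 1 || t == 2) {
            dx += drift_right[k] ? DRIFT : -DRIFT;
            pushed = true;
          }
          break;
        }
      }
    }
    x += dx;
    y = y2;

    // visibility counts: obstacles with oy in (y - 306, y + 540)
    size_t vlo = std::upper_bound(oy_sorted.begin(), oy_sorted.end(), y - 306.0) -
                 oy_sorted.begin();
    size_t vhi = std::lower_bound(oy_sorted.begin(), oy_sorted.end(), y + 540.0) -
                 oy_sorted.begin();
    int n_on = (int)(vhi - vlo);
    int n_dron = 0;
    for (int k = 0; k < n_dr; ++k)
      if (drift_y[k] > y - 540.0 && drift_y[k] < y + 540.0) ++n_dron;

    frame[i] = i + 1;
    xs[i] = x; ys[i] = y; key_out[i] = key; dxs[i] = dx;
    drift_act[i] = pushed; nob[i] = n_on; ndr[i] = n_dron;
    control[i] = !is_entry;
    ++i;

    if (!is_entry) {
      // collision: walls or any obstacle with |x-ox|<36 and |y-oy|<36
      bool hit = (x < 0.0) || (x + SHIP > width_px);
      if (!hit) {
        size_t clo = std::upper_bound(oy_sorted.begin(), oy_sorted.end(), y - SHIP) -
                     oy_sorted.begin();
        for (size_t k = clo; k < (size_t)n_obs && oy_sorted[k] < y + SHIP; ++k) {
          if (std::fabs(x - ox_by_y[k]) < SHIP) { hit = true; break; }
        }
      }
      if (hit) {
        completed = false;
        crash_frame = i;
        break;
      }
    }
  }

  Range r(0, i - 1);
  return List::create(
      _["frame"] = frame[r], _["x"] = xs[r], _["y"] = ys[r],
      _["key"] = key_out[r], _["dx"] = dxs[r],
      _["drift_active"] = drift_act[r],
      _["n_obstacles_on_screen"] = nob[r],
      _["n_drift_sections_on_screen"] = ndr[r],
      _["control"] = control[r],
      _["completed"] = completed, _["crash_frame"] = crash_frame);
}
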