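#include <Rcpp.h>
#include <vector>
#include <utility>

using namespace Rcpp;

// Neighbour offsets in the order x1=E, x2=NE, x3=N, x4=NW, x5=W, x6=SW,
// x7=S, x8=SE (counter-clockwise from east), as used by the Yokoi
// connectivity number.
static const int DR[8] = { 0, -1, -1, -1,  0,  1,  1,  1 };
static const int DC[8] = { 1,  1,  0, -1, -1, -1,  0,  1 };

static inline bool at(const std::vector<char>& m, int H, int W, int r, int c) {
    if (r < 0 || r >= H || c < 0 || c >= W) return false;
    return m[(size_t)r * W + c] != 0;
}

// Yokoi connectivity number for 8-connected foreground.  A foreground
// pixel is "simple" (deletable without changing topology) iff C == 1.
static inline int yokoi8(const std::vector<char>& m, int H, int W, int r, int c) {
    int x[8];
    for (int k = 0; k < 8; ++k) x[k] = at(m, H, W, r + DR[k], c + DC[k]) ? 1 : 0;
    int C = 0;
    for (int k = 0; k < 8; k += 2) {   // k = E, N, W, S (4-neighbours)
        int xb0 = 1 - x[k];
        int xb1 = 1 - x[(k + 1) % 8];
        int xb2 = 1 - x[(k + 2) % 8];
        C += xb0 - xb0 * xb1 * xb2;
    }
    return C;
}

static inline int ncount(const std::vector<char>& m, int H, int W, int r, int c) {
    int n = 0;
    for (int k = 0; k < 8; ++k)
        if (at(m, H, W, r + DR[k], c + DC[k])) ++n;
    return n;
}

//' @title Topology-preserving thinning (internal kernel)
//' @description Border-sequential thinning of a binary image down to a
//'   one-pixel-wide, 8-connected skeleton.  In each iteration four
//'   directional subiterations (north, south, west, east) delete border
//'   pixels that are simple points (Yokoi 8-connectivity number equal to 1)
//'   and not line endpoints; the border set of each subiteration is frozen
//'   at its start so at most one pixel layer is removed per pass.
//' @param mask integer/logical matrix, nonzero = foreground
//' @return integer matrix of 0/1, same shape
//' @keywords internal
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
    const int H = mask.nrow(), W = mask.ncol();
    std::vector<char> m((size_t)H * W);
    for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c)
            m[(size_t)r * W + c] = mask(r, c) != 0 ? 1 : 0;

    // subiteration directions: pixel is border if its neighbour in this
    // direction is background
    const int sdr[4] = { -1, 1, 0, 0 };
    const int sdc[4] = { 0, 0, -1, 1 };

    std::vector<std::pair<int,int> > border;
    bool changed = true;
    while (changed) {
        changed = false;
        for (int s = 0; s < 4; ++s) {
            border.clear();
            for (int r = 0; r < H; ++r)
                for (int c = 0; c < W; ++c)
                    if (m[(size_t)r * W + c] &&
                        !at(m, H, W, r + sdr[s], c + sdc[s]))
                        border.push_back(std::make_pair(r, c));
            for (size_t i = 0; i < border.size(); ++i) {
                int r = border[i].first, c = border[i].second;
                if (!m[(size_t)r * W + c]) continue;
                int n = ncount(m, H, W, r, c);
                if (n <= 1) continue;                 // endpoint or isolated
                if (yokoi8(m, H, W, r, c) == 1) {     // simple point
                    m[(size_t)r * W + c] = 0;
                    changed = true;
                }
            }
        }
    }

    IntegerMatrix out(H, W);
    for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c)
            out(r, c) = m[(size_t)r * W + c];
    return out;
}

//' @title 8-connected component labelling (internal kernel)
//' @param mask integer/logical matrix, nonzero = foreground
//' @return integer matrix of labels, 0 = background, components numbered
//'   from 1 in scan order
//' @keywords internal
// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(IntegerMatrix mask) {
    const int H = mask.nrow(), W = mask.ncol();
    IntegerMatrix lab(H, W);
    std::vector<std::pair<int,int> > stack;
    int next = 0;
    for (int r0 = 0; r0 < H; ++r0) {
        for (int c0 = 0; c0 < W; ++c0) {
            if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
            ++next;
            stack.clear();
            stack.push_back(std::make_pair(r0, c0));
            lab(r0, c0) = next;
            while (!stack.empty()) {
                std::pair<int,int> p = stack.back();
                stack.pop_back();
                for (int k = 0; k < 8; ++k) {
                    int r = p.first + DR[k], c = p.second + DC[k];
                    if (r < 0 || r >= H || c < 0 || c >= W) continue;
                    if (mask(r, c) != 0 && lab(r, c) == 0) {
                        lab(r, c) = next;
                        stack.push_back(std::make_pair(r, c));
                    }
                }
            }
        }
    }
    return lab;
}
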