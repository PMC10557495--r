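---
title: "Separating pulmonary arteries and veins from vessel topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating pulmonary arteries and veins from vessel topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In non-contrast chest CT, pulmonary arteries and veins have nearly the same
intensity, run close together, and intertwine. Separating them matters for
surgical planning, but per-voxel classifiers ignore the one structure that
makes the problem tractable: vessels form trees. avtopo implements an
artery/vein (A/V) separation pipeline that works *on the vessel tree*: it
extracts a centerline topology graph from a binary vessel mask, scores every
centerline sample ("particle") with a learned classifier, and then enforces
tree-level consistency with a topology optimizer. A synthetic phantom
generator with exact ground truth makes every stage testable without
clinical data.

The pipeline consumes a vessel mask (plus, optionally, the CT intensities);
producing that mask by segmentation is out of scope.

## Vessel-tree topology extraction

**Particles.** Centerline samples are localized as ridge maxima of a
multiscale Hessian vesselness measure. By default the vesselness substrate
is the mask's exact Euclidean distance transform: its ridge *is* the medial
axis, and unlike the smoothed binary mask it peaks on the axis at every
scale. At each scale $\sigma$ (a geometric ladder from 1 mm up to the
largest inscribed radius) the substrate is Gaussian-smoothed, the
$\sigma^2$-normalized Hessian is diagonalized, and the standard tubular
(bright-ridge) vesselness is evaluated; each voxel keeps its best scale.
A voxel becomes a particle when its response is maximal among the
cross-sectional neighbors (those at |cos| < 0.6 to the local axis, which is
the eigenvector of the smallest-magnitude eigenvalue). Particles are thinned
to ~1 voxel spacing. Each particle carries position, orientation, the image
intensity, and a **scale** equal to the distance-transform value at its
position — the inscribed radius, which is what downstream consumers (the
tubule threshold, the reconstruction ball) actually need; the argmax
$\sigma$ is kept in a separate column.

**Arrival-time map.** The Eikonal equation $|\nabla T|\,F = 1$ is solved by
multi-stencils fast marching with second-order upwind differences on four
orthogonal frames (axes plus the three face-diagonal frames). The speed is
$F = d^{\,p}$ with $d$ the distance map and $p = 1$ by default, so fronts
travel fastest along the medial axis and minimal paths hug the centerline.
One source per mask component is used: the component's distance-map maximum
(the thickest, most proximal point), with ties resolved to the voxel closest
to the centroid of the tied set. Two numerical caveats are documented rather
than hidden: (a) frames through the body diagonals would need non-orthogonal
metric terms, so along body-diagonal directions the solver retains a
few-percent directional bias; (b) in the one-voxel boundary shell the
discrete solution differs noticeably from a voxel-graph (Dijkstra) oracle
because the two schemes resolve the steep speed falloff differently. The
test suite therefore checks solver/oracle agreement (within 5%) in the lumen
core, the regime where traced paths actually live.

**Terminals, tracing and repair.** Candidate terminals are local maxima of
the arrival time, non-maximum suppressed within twice the local radius and
pruned of shallow maxima below 15% of the maximal arrival time (terminals
are the *farthest* leaf points). `backtrace()` descends the time map by
steepest per-mm decrease and reports an online confidence — the
trailing-window mean (window 5) of the per-step decrease normalized by the
local inverse speed; a trace whose confidence falls below 0.1 is flagged as
a spurious leaf. Both constants are exposed arguments; the stopping rule is
a documented package convention.

Particle sampling loses points where vessels are not tubular — most often at
bifurcations. Repair has two phases. First, every Ω26-terminal probes along
its outward axis at 1–2 × scale; if the probe still lands on the mask the
terminal is a false positive, and the trajectory recovered by descending the
time map is inserted as new particles (scale interpolated from the distance
map). The probe direction is the orientation sign that points *away* from
the mean neighbor position — probing both signs indiscriminately would flag
every true terminal too, since the inward probe always lands on mask.
Second, any remaining particle fragment that does not contain its mask
component's earliest-arrival particle descends the time map from its own
earliest particle until it meets another fragment. After repair the particle
components match the mask components one-to-one.

**Graph.** Candidate edges join particles within 3 × the median
nearest-neighbor spacing; a degree-capped Kruskal spanning forest (shortest
edges first; an edge is accepted only if it joins two trees and neither
endpoint already has 3 edges) produces an acyclic graph with node degrees in
[1, 3] *by construction* — cutting a spanning tree afterwards can disconnect
branches at junction clusters. The Ω26 particle-kind classification
(1 neighbor = terminal, 2 = branching, >2 = bifurcating) uses 1.5 × the
median nearest-neighbor spacing, floored at the voxel diagonal $\sqrt3$
(at ~1-voxel sampling a literal 26-neighborhood spans the diagonal).
Junction bulges shed 1–3-particle terminal twigs; image-based extraction
prunes these spurs (threshold 3 particles; genuine branches are several
radii long, so they are never this short).

## Twin-pipe classifier

Every particle is scored by a non-local CNN + GCN pair. Oriented patches of
size 32 × 32 × 3 (three planes perpendicular to the vessel axis, one voxel
apart) are sampled by trilinear interpolation, with two choices that follow
from the geometry of the discriminative cue — the dark companion bronchus
that accompanies arteries at a center offset of ~1.5 vessel radii:

* **Scale-normalized sampling.** The in-plane step is scale/4 voxels
  (floored at 0.4), so every patch spans ±4 radii and the bronchus sits at a
  fixed relative radius regardless of vessel size. At a fixed 32-voxel
  window the patch would be dominated by unrelated neighboring structures
  for small vessels.
* **Radial positional encoding.** An extra channel holding each position's
  normalized distance from the patch center lets position-wise layers form
  "dark *and* near the center" conjunctions; without it, pooling erases
  position identity.

Patches are windowed to [−1000, 400], rescaled to [0, 1], average-pooled
4 × 4 to 8 × 8 positions and standardized per channel (statistics frozen
into the classifier state). The feature extractor Φ is one position-wise
ReLU layer (d = 24) followed by an embedded-Gaussian self-attention block
with residual connection and global average pooling; the per-node features
Y then pass through two graph-convolution layers
$H^{(l+1)} = \sigma(W H^{(l)} \Theta^{(l)})$ over the center + 2-neighbor
star of each node ($W$ is the symmetrically normalized adjacency with self
loops; absent neighbors contribute zero features). Two initialization
choices matter at this training scale: the position-wise layer starts as a
bank of randomly *thresholded* detectors (unit-normal weights, biases
uniform in ±1.5), and the attention output matrix starts at zero so the
block is an exact passthrough at initialization. Deeper stacks were tried
and plateau; this shallow residual form is the one that trains.

Training uses SGD with momentum 0.9, learning rate 1e-3, batch size 128 and
cross-entropy, with class-balanced batches. The reference schedule is 150
epochs; the package default is 50, which is where the desk-scale corpus
(20 phantoms of 64³ voxels) converges within its runtime budget. All
gradients are hand-derived and checked against finite differences in the
test suite.

The **twin-pipe** arrangement trains one pipe on all vessels (CT patches)
and a second on the tubule subgraph — the branches with median radius below
2.5 voxels — with two-channel patches (CT + multiscale vessel enhancement).
Predictions merge by mutual correction: on tubule nodes, when the pipes
disagree on the class and the tubule pipe is more extreme
(|p − 0.5| larger), the tubule prediction wins (λ = 1); otherwise they are
averaged (λ = 0.5). Non-tubule nodes keep the full-pipe probability. The
λ rule is a documented stand-in for an unspecified mechanism and is fully
configurable. An **oracle classifier** (ground truth + configurable flip
noise) sits behind the same probability interface so the optimizer can be
exercised without any training.

## Topology optimizer

Thresholding at p > 0.5 (ties to vein) gives preliminary classes. Branches
— maximal chains between terminals and junctions — are single-vessel by
construction. Subtrees partition the non-trunk graph: structural subtree
roots start each branch at trunk depth 2 (configurable), and, optionally,
every node where the label majority of the descendant set flips relative to
its parent's becomes an additional root. Each subtree votes by particle
majority (ties resolve to the root branch's class, then to vein); branch
and subtree confidences are the majority fraction, damped by
min(1, n/3) so one- and two-particle groups cannot dominate.

Conflicts are resolved distal-first: a branch whose class disagrees with its
subtree is **pruned** — re-rooted as its own subtree, keeping its class,
its distal descendant branches moving with it — when its damped confidence
exceeds the subtree's, and relabeled to the subtree class otherwise.
Finally every particle takes its branch class; a bifurcation node, which is
shared by parent and child branches, takes the parent branch's class.
Every correction lands in an audit log.

Two design choices deserve emphasis. First, the label-driven flip-detection
refinement is the *static* analogue of pruning; the full optimizer therefore
starts from purely structural subtrees and performs the splitting
dynamically under confidence control — running both would let noise-created
micro-subtrees overrule correct branches. The subtree-only ablation arm, by
contrast, uses flip detection, since that is all a subtree-level method has.
Second, the four ablation arms (`particle`, `subtree`, `branch`, `full`)
are first-class modes, and on noisy oracle labels their mean accuracies
order exactly this way — the property the test suite asserts.

## Reconstruction and evaluation

Labels are painted back to voxels: each mask voxel takes the class of the
nearest particle whose scale ball (radius = scale × 1.25) covers it, and
uncovered voxels take the label of the geodesically nearest covered voxel
within the mask (multi-source BFS), so the painted volume always partitions
the mask. Hilum label volumes, when supplied, win on overlap — vessels near
the hilum are large and non-tubular, so topology-derived labels are less
trustworthy there. Evaluation is particle-first (accuracy, sensitivity and
specificity with arteries positive), with per-class voxel Dice as the
secondary surface.

## The phantom generator

The phantom is the study condition, not a tuning knob. Two binary trees
(artery, vein) grow side by side with Murray's law radii
($r_p^3 = r_1^3 + r_2^3$; exponent configurable), branch lengths of 4–10
radii (4–6.5 in the smaller corpora so depth-3 trees fit a 64³–96³ box),
branching angles of 20–40°, and minor/major radius ratios of 0.7–1. The
pair is entangled: all inter-tree branch surfaces keep a 2 mm clearance
except for a configurable number of adhesion sites, where a vein control
point is pulled onto the nearest artery branch until the surfaces touch.
Rasterization paints tapering capsules (nearest surface wins where they
overlap), samples ground-truth centerlines at 0.5 mm, and adds a companion
"bronchus" tube along every arterial branch: center offset 1.5 ×, radius
0.8 × the local artery radius, carved so it never overlaps the vessel mask.
By default every arterial branch gets a companion — the phantom emulates the
intrapulmonary region where arterial-bronchial accompaniment holds; a
finite threshold radius reproduces the near-hilum breakdown. Pseudo-CT
intensities are +50 HU-like for vessels, −800 for parenchyma, −950 for the
bronchus lumen, with Gaussian noise (σ = 20); an artery intensity shift
emulates a contrast-enhanced arterial phase. Everything is reproducible
bit-for-bit from one seed.

What the phantom does *not* emulate: lobar anatomy, respiratory motion,
scanner artifacts, partial-volume effects at real slice thickness, or the
irregular wall apposition of real A/V crossings. Passing tests on phantoms
demonstrates that the algorithms do what they claim under known geometry,
not clinical-grade performance.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberate desk scales: 96³
phantoms (depth 3) for topology recovery, 20 seeds for the optimizer
ordering, a 20-phantom 64³ corpus (14 train / 6 held out, split at the
phantom level so no particle leaks across) for classifier training, and
≤32³ tubes for the Eikonal oracle. Grids are R-native `[x, y, z]` arrays
with 1-based voxel indices and physical coordinates `(index − 1) × spacing`
(mm). All tie-breaks resolve deterministically (vein for 50/50 votes,
index order for spatial ties); every stochastic step takes an explicit
seed, and the pipeline derives per-stage seeds from one master seed so
stages can be rerun independently.

## Known limitations

* Particle scales at adhesions and crossings are unreliable (the inscribed
  sphere spans both vessels); reconstruction there can bulge. Logged, not
  fixed.
* The fast-marching solver's directional bias along body diagonals (see
  above) is a property of the diagonal-frame stencil set.
* The classifier is desk-scale by design; its accuracy ceiling on real CT
  is untested and the phantom's bronchus cue is cleaner than real anatomy.
* Subtree extraction assumes a rooted forest; masks whose components touch
  (adhesions) yield mixed components that rely on the optimizer's pruning
  rather than component purity.
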