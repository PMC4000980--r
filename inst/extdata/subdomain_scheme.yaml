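# Hanks-Hunter subdomain segmentation convention, anchored on the five
# canonical catalytic motifs. Boundaries between anchors are a documented
# convention (calibrated so that the EGFR gatekeeper/hinge residues 790-796
# fall in subdomain V); results that depend on region boundaries should be
# reported together with this scheme version.
version: 1
nterm_pad: 4            # residues of subdomain I kept before the P-loop glycine
ploop_len: 6            # G-x-G-x-x-G
vaik_len: 4             # V-A-I-K (beta3; the catalytic lysine is the 4th residue)
split_fractions: [0.22, 0.45, 0.60]  # III/IV/V/VIa cuts across the VAIK->HRD span
vib_width: 8            # catalytic loop (HRD...) width
cterm_widths:           # fixed widths downstream of the APE motif
  IX: 12
  X(i): 9
  X(ii): 9
  XI: 17
column_base:            # alignment-column base per anchor frame
  ploop: 1000
  vaik: 2000
  hrd: 3000
  dfg: 4000
  ape: 5000
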