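# Fluoropyrimidine target panel: 5-fluorouracil, five of its metabolites
# and the two endogenous nucleotides monitored alongside them.
# precursor_mz is the published fingerprint [M-H]- value; fragments are
# the published fingerprint transition m/z values (semicolon separated);
# rt_min is the observed retention time on the F5 column (NA = analyte
# not detected in the original assay, simulator-only default used).
# note: FdUMP and FdURD also circulated on an inclusion list as 325.0211
# and 245.0605; those entries contradict their own scan-filter centers
# (325.0240, 245.0570) and the exact masses, and are treated as
# typographical. Both alternates are recorded in alt_mz for provenance.
compound	formula	precursor_mz	alt_mz	rt_min	fragments
5-FU	C4H3FN2O2	129.0109	NA	1.6	58.993
FdUMP	C9H12FN2O8P	325.024	325.0211	1.4	195.006;129.01;96.969;78.959
FURD	C9H11FN2O6	261.0529	NA	1.9	171.021;129.009;108.009;84.025
FdURD	C9H11FN2O5	245.057	245.0605	2.1	155.025;129.009;112.0204
FUTP	C9H14FN2O15P3	500.9517	NA	NA	482.9407;158.900;129.01
FdUTP	C9H14FN2O14P3	484.956	NA	NA	441.9506;256.80;129.01
dUMP	C9H13N2O8P	307.0338	NA	1.4	195.006;111.02;96.9696
TMP	C10H15N2O8P	321.0497	NA	1.5	195.005;125.0355;96.9691
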