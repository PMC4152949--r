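# Default dinucleotide structural-property table (SYNTHETIC STAND-IN).
# Six local structural descriptors of the dinucleotide step: angular
# (twist, tilt, roll; degrees) and translational (shift, slide, rise;
# Angstrom). These values were constructed by the package authors to lie
# in the ranges reported by crystallographic dinucleotide-step analyses
# and to respect reverse-complement symmetry (tilt and shift change sign,
# the other four are invariant). They are NOT the published table of any
# specific study; to reproduce published PseDNC results, supply that
# study's table via read_property_table().
dinucleotide	twist	tilt	roll	shift	slide	rise
AA	35.6	-1.4	0.7	0.07	-0.08	3.27
AC	34.4	-0.6	0.7	0.14	-0.58	3.36
AG	27.7	-1.7	4.5	0.04	-0.25	3.34
AT	31.5	0.0	1.1	0.00	-0.59	3.31
CA	34.5	-0.3	4.7	0.10	0.53	3.33
CC	33.7	-0.1	3.6	-0.02	-0.22	3.42
CG	29.8	0.0	5.4	0.00	0.41	3.39
CT	27.7	1.7	4.5	-0.04	-0.25	3.34
GA	36.9	-1.5	1.9	0.11	-0.03	3.37
GC	40.0	0.0	0.3	0.00	-0.38	3.40
GG	33.7	0.1	3.6	0.02	-0.22	3.42
GT	34.4	0.6	0.7	-0.14	-0.58	3.36
TA	36.0	0.0	3.3	0.00	0.05	3.42
TC	36.9	1.5	1.9	-0.11	-0.03	3.37
TG	34.5	0.3	4.7	-0.10	0.53	3.33
TT	35.6	1.4	0.7	-0.07	-0.08	3.27
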