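# van der Waals radii dictionary
# dialect: RESIDUE ATOM RADIUS  (whitespace separated, '#' comments)
#   - residue-specific lines override everything for that (residue, atom)
#   - GENERIC <ELEMENT> lines are per-element fallbacks
#   - GENERIC * is the last-resort default (must be present)
# Element radii follow Bondi (1964) with the common Rowland-Taylor H value.
GENERIC H  1.20
GENERIC D  1.20
GENERIC C  1.70
GENERIC N  1.55
GENERIC O  1.52
GENERIC S  1.80
GENERIC P  1.80
GENERIC F  1.47
GENERIC CL 1.75
GENERIC BR 1.85
GENERIC I  1.98
GENERIC SE 1.90
GENERIC B  1.92
GENERIC ZN 1.39
GENERIC MG 1.73
GENERIC CA 2.31
GENERIC NA 2.27
GENERIC K  2.75
GENERIC FE 1.60
GENERIC MN 1.61
GENERIC CU 1.40
GENERIC * 1.70
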