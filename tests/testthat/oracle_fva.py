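"""Per-reaction two-LP brute-force FVA oracle via scipy (HiGHS)."""
import json
import sys

import numpy as np
from scipy.optimize import linprog

cases = json.load(open(sys.argv[1]))
out = []
for cs in cases:
    A = np.array(cs["A"], dtype=float)
    b = np.array(cs["b"], dtype=float)
    bounds = list(zip(cs["lower"], cs["upper"]))
    n = A.shape[1]
    vmin, vmax = [], []
    for j in range(n):
        c = np.zeros(n)
        c[j] = 1.0
        lo = linprog(c, A_eq=A, b_eq=b, bounds=bounds, method="highs")
        hi = linprog(-c, A_eq=A, b_eq=b, bounds=bounds, method="highs")
        if lo.status != 0 or hi.status != 0:
            vmin.append(None)
            vmax.append(None)
        else:
            vmin.append(lo.fun)
            vmax.append(-hi.fun)
    out.append({"min": vmin, "max": vmax})
json.dump(out, open(sys.argv[2], "w"))
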