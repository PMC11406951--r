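"""Batch LP oracle: scipy.optimize.linprog (HiGHS) over JSON-encoded cases."""
import json
import sys

import numpy as np
from scipy.optimize import linprog

cases = json.load(open(sys.argv[1]))
status_out, obj_out = [], []
for cs in cases:
    A = np.array(cs["A"], dtype=float)
    obj = np.array(cs["obj"], dtype=float)
    maximize = bool(cs["maximize"][0])
    c = -obj if maximize else obj
    res = linprog(c, A_eq=A, b_eq=np.array(cs["b"], dtype=float),
                  bounds=list(zip(cs["lower"], cs["upper"])), method="highs")
    if res.status == 0:
        status_out.append("optimal")
        obj_out.append(-res.fun if maximize else res.fun)
    elif res.status == 2:
        status_out.append("infeasible")
        obj_out.append(None)
    else:
        status_out.append("other")
        obj_out.append(None)
json.dump({"status": status_out, "objective": obj_out}, open(sys.argv[2], "w"))
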