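# Generic convex-programming oracle for the weighted fused lasso proximal
# problem: minimize 0.5*mu*||a - z||^2 + l1*sum|z| + l2*sum_{k<k'}|z_k-z_k'|
# via the smooth epigraph QP solved by scipy SLSQP. Used only as an
# independent cross-check in the test suite.
import json
import sys

import numpy as np
from scipy.optimize import minimize


def solve(a, l1, l2, mu):
    a = np.asarray(a, float)
    K = len(a)
    pairs = [(i, j) for i in range(K) for j in range(i + 1, K)]
    nv = len(pairs)

    def obj(x):
        z = x[:K]
        return 0.5 * mu * np.sum((a - z) ** 2) + l1 * np.sum(x[K:2 * K]) \
            + l2 * np.sum(x[2 * K:])

    def grad(x):
        z = x[:K]
        return np.concatenate([mu * (z - a), l1 * np.ones(K), l2 * np.ones(nv)])

    cons = []
    for k in range(K):
        cons.append({'type': 'ineq', 'fun': (lambda x, k=k: x[K + k] - x[k])})
        cons.append({'type': 'ineq', 'fun': (lambda x, k=k: x[K + k] + x[k])})
    for q, (i, j) in enumerate(pairs):
        cons.append({'type': 'ineq',
                     'fun': (lambda x, i=i, j=j, q=q: x[2 * K + q] - (x[i] - x[j]))})
        cons.append({'type': 'ineq',
                     'fun': (lambda x, i=i, j=j, q=q: x[2 * K + q] + (x[i] - x[j]))})
    x0 = np.concatenate([a, np.abs(a), [abs(a[i] - a[j]) for i, j in pairs]])
    res = minimize(obj, x0, jac=grad, constraints=cons, method='SLSQP',
                   options={'maxiter': 500, 'ftol': 1e-14})
    return res.x[:K].tolist()


if __name__ == '__main__':
    problems = json.load(open(sys.argv[1]))
    out = [solve(np.atleast_1d(p['a']),
                 float(np.ravel(p['l1'])[0]),
                 float(np.ravel(p['l2'])[0]),
                 float(np.ravel(p['mu'])[0])) for p in problems]
    json.dump(out, open(sys.argv[2], 'w'))
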