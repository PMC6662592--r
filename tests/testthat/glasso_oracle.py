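# Established graphical-lasso reference (scikit-learn) used as the
# independent oracle for the single-state, no-pathway, no-prior reduction.
import sys

import numpy as np
from sklearn.covariance import graphical_lasso

S = np.loadtxt(sys.argv[1])
alpha = float(sys.argv[3])
cov, prec = graphical_lasso(S, alpha=alpha, tol=1e-10, max_iter=2000)
np.savetxt(sys.argv[2], prec)
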