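model_no,label,aicc,delta_aicc,k,deviance
1,phi(a2 a+t) p(T3) psi(4 ln),1816.37,0.00,18,1786.27
2,phi(a2 a*t) p(T3) psi(4 ln),1817.77,1.40,26,1769.53
3,phi(a2 a*t) p(t) psi(4 ln),1817.81,1.44,31,1767.55
4,phi(a2 a*t) p(t) psi(4 lin),1820.72,4.35,31,1770.46
5,phi(a2 a*t) p(t) psi(5),1821.28,4.91,34,1762.94
6,phi(a2 a*t) p(t) psi(4),1823.01,6.64,33,1766.69
7,phi(a2 a*t) p(t) psi(3),1843.22,26.85,32,1790.95
8,phi(a3 a*t) p(t) psi(5),1872.68,56.31,42,1814.34
9,phi(a1 t) p(t) psi(5),1931.00,114.63,25,1890.83
10,phi(a2 a*t) p(.) psi(4 ln),2411.78,595.41,23,2373.63
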