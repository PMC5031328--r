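aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.325	-0.665	0.109	0.105	-0.613	-0.16	-0.244	-0.604	0.14	-0.612	-0.562	-0.039	-0.131	-0.051	0.02	-0.071	-0.033	-0.557	-0.563	-0.408
C	-0.665	-1.346	0.218	0.207	-1.265	-0.355	-0.477	-1.171	0.305	-1.231	-1.132	-0.098	-0.234	-0.105	0.049	-0.139	-0.059	-1.091	-1.101	-0.831
D	0.109	0.218	0.303	0.317	0.202	0.058	-0.096	0.212	-0.402	0.214	0.203	0.013	0.045	0.007	-0.36	0.017	0.025	0.177	0.192	0.129
E	0.105	0.207	0.317	0.316	0.187	0.04	-0.106	0.172	-0.382	0.175	0.19	0.001	0.047	0.021	-0.37	0.024	-0.005	0.166	0.163	0.132
F	-0.613	-1.265	0.202	0.187	-1.155	-0.327	-0.431	-1.102	0.275	-1.141	-1.067	-0.075	-0.229	-0.095	0.061	-0.13	-0.058	-1.015	-1.047	-0.791
G	-0.16	-0.355	0.058	0.04	-0.327	-0.09	-0.126	-0.297	0.089	-0.306	-0.283	-0.014	-0.052	-0.034	0.002	-0.025	-0.001	-0.282	-0.273	-0.214
H	-0.244	-0.477	-0.096	-0.106	-0.431	-0.126	-0.067	-0.396	0.282	-0.412	-0.379	-0.031	-0.089	-0.028	0.21	-0.053	-0.01	-0.385	-0.397	-0.284
I	-0.604	-1.171	0.212	0.172	-1.102	-0.297	-0.396	-1.042	0.256	-1.077	-1	-0.078	-0.208	-0.116	0.042	-0.127	-0.037	-0.971	-0.993	-0.735
K	0.14	0.305	-0.402	-0.382	0.275	0.089	0.282	0.256	0.299	0.274	0.234	0.034	0.06	0.015	0.325	0.023	0.026	0.246	0.233	0.168
L	-0.612	-1.231	0.214	0.175	-1.141	-0.306	-0.412	-1.077	0.274	-1.092	-1.017	-0.092	-0.199	-0.094	0.038	-0.121	-0.05	-0.989	-1.007	-0.761
M	-0.562	-1.132	0.203	0.19	-1.067	-0.283	-0.379	-1	0.234	-1.017	-0.973	-0.091	-0.206	-0.097	0.059	-0.12	-0.046	-0.907	-0.932	-0.704
N	-0.039	-0.098	0.013	0.001	-0.075	-0.014	-0.031	-0.078	0.034	-0.092	-0.091	-0.018	-0.015	0.008	0.006	-0.002	-0.011	-0.08	-0.077	-0.057
P	-0.131	-0.234	0.045	0.047	-0.229	-0.052	-0.089	-0.208	0.06	-0.199	-0.206	-0.015	-0.038	-0.029	0.022	-0.027	0.003	-0.182	-0.177	-0.129
Q	-0.051	-0.105	0.007	0.021	-0.095	-0.034	-0.028	-0.116	0.015	-0.094	-0.097	0.008	-0.029	-0.024	-0.004	-0.006	-0.019	-0.093	-0.088	-0.073
R	0.02	0.049	-0.36	-0.37	0.061	0.002	0.21	0.042	0.325	0.038	0.059	0.006	0.022	-0.004	0.337	0.009	0.014	0.062	0.048	0.05
S	-0.071	-0.139	0.017	0.024	-0.13	-0.025	-0.053	-0.127	0.023	-0.121	-0.12	-0.002	-0.027	-0.006	0.009	0	-0.013	-0.111	-0.113	-0.081
T	-0.033	-0.059	0.025	-0.005	-0.058	-0.001	-0.01	-0.037	0.026	-0.05	-0.046	-0.011	0.003	-0.019	0.014	-0.013	0.004	-0.036	-0.049	-0.042
V	-0.557	-1.091	0.177	0.166	-1.015	-0.282	-0.385	-0.971	0.246	-0.989	-0.907	-0.08	-0.182	-0.093	0.062	-0.111	-0.036	-0.872	-0.903	-0.669
W	-0.563	-1.101	0.192	0.163	-1.047	-0.273	-0.397	-0.993	0.233	-1.007	-0.932	-0.077	-0.177	-0.088	0.048	-0.113	-0.049	-0.903	-0.937	-0.682
Y	-0.408	-0.831	0.129	0.132	-0.791	-0.214	-0.284	-0.735	0.168	-0.761	-0.704	-0.057	-0.129	-0.073	0.05	-0.081	-0.042	-0.669	-0.682	-0.512
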