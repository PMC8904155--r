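# Voltage-dependent gating kinetics, one record per (gate, role).
# Gates: m,h = Na activation/inactivation; n = delayed-rectifier K;
#        a,ha = A-type K activation/inactivation; c = L-type Ca activation;
#        q = HCN (h-current) activation; tm,th = low-threshold T-type Ca gates.
# Roles alpha/beta give rate constants [1/ms] directly; roles inf/tau give the
# steady state [dimensionless] and time constant [ms], from which
# alpha = inf/tau, beta = (1-inf)/tau.
# Rate forms (V in mV):
#   linexp  : p1*(V-p2)/(1 - exp(-(V-p2)/p3)), value p1*p3 at V = p2
#   expdec  : p1*exp(-(V-p2)/p3)
#   sigmoid : p1/(1 + exp(-(V-p2)/p3))
#   siginf  : 1/(1 + exp((V-p1)/p2))          (inf role only)
#   taugauss: p1 + p2*exp(-((V-p3)/p4)^2)     (tau role only)
# m,h,n,a,ha,c follow the Fohlmeister-Miller (1997) RGC rate equations; q and
# tm/th are standard HCN and low-threshold Ca forms (see package vignette).
gate,role,form,p1,p2,p3,p4
m,alpha,linexp,0.6,-30,10,0
m,beta,expdec,20,-55,18,0
h,alpha,expdec,0.4,-50,20,0
h,beta,sigmoid,6,-20,10,0
n,alpha,linexp,0.02,-40,10,0
n,beta,expdec,0.4,-50,80,0
a,alpha,linexp,0.006,-90,10,0
a,beta,expdec,0.1,-30,10,0
ha,alpha,expdec,0.04,-70,20,0
ha,beta,sigmoid,0.6,-40,10,0
c,alpha,linexp,0.3,-13,10,0
c,beta,expdec,10,-38,18,0
q,inf,siginf,-80,8,0,0
q,tau,taugauss,100,900,-80,25
tm,inf,siginf,-45,-7.4,0,0
tm,tau,taugauss,0.3,0.7,-90,25
th,inf,siginf,-80,5,0,0
th,tau,taugauss,28,85,-52,25
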