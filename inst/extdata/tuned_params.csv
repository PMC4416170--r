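method,param,featureset,value
MARS,degree,X,2
MARS,degree,A,1
MARS,degree,R,1
MARS,degree,G,1
MARS,degree,XA,1
MARS,degree,XR,1
MARS,degree,XG,1
MARS,degree,AR,1
MARS,degree,AG,1
MARS,degree,RG,1
MARS,degree,XAR,1
MARS,degree,XAG,1
MARS,degree,XRG,1
MARS,degree,ARG,1
MARS,degree,XARG,1
MARS,penalty,X,2
MARS,penalty,A,6
MARS,penalty,R,5
MARS,penalty,G,6
MARS,penalty,XA,7
MARS,penalty,XR,2
MARS,penalty,XG,6
MARS,penalty,AR,7
MARS,penalty,AG,6
MARS,penalty,RG,5
MARS,penalty,XAR,6
MARS,penalty,XAG,7
MARS,penalty,XRG,6
MARS,penalty,ARG,5
MARS,penalty,XARG,6
kNN,k,X,15
kNN,k,A,13
kNN,k,R,14
kNN,k,G,16
kNN,k,XA,9
kNN,k,XR,19
kNN,k,XG,17
kNN,k,AR,19
kNN,k,AG,18
kNN,k,RG,17
kNN,k,XAR,18
kNN,k,XAG,19
kNN,k,XRG,17
kNN,k,ARG,18
kNN,k,XARG,19
kNN,q,X,1
kNN,q,A,1
kNN,q,R,1
kNN,q,G,1
kNN,q,XA,1
kNN,q,XR,1
kNN,q,XG,1
kNN,q,AR,1
kNN,q,AG,1
kNN,q,RG,1
kNN,q,XAR,1
kNN,q,XAG,1
kNN,q,XRG,1
kNN,q,ARG,1
kNN,q,XARG,1
SVM,C,X,2
SVM,C,A,2
SVM,C,R,1
SVM,C,G,1
SVM,C,XA,1
SVM,C,XR,4
SVM,C,XG,1
SVM,C,AR,2
SVM,C,AG,2
SVM,C,RG,1
SVM,C,XAR,1
SVM,C,XAG,2
SVM,C,XRG,2
SVM,C,ARG,1
SVM,C,XARG,2
SVM,epsilon,X,0.5
SVM,epsilon,A,0
SVM,epsilon,R,0.25
SVM,epsilon,G,0.25
SVM,epsilon,XA,0.125
SVM,epsilon,XR,0.125
SVM,epsilon,XG,0.25
SVM,epsilon,AR,0.25
SVM,epsilon,AG,0.25
SVM,epsilon,RG,0.125
SVM,epsilon,XAR,0.25
SVM,epsilon,XAG,0.125
SVM,epsilon,XRG,0.125
SVM,epsilon,ARG,0.125
SVM,epsilon,XARG,0.25
SVM,sigma,X,1
SVM,sigma,A,0.25
SVM,sigma,R,0.125
SVM,sigma,G,0.25
SVM,sigma,XA,0.25
SVM,sigma,XR,0.031
SVM,sigma,XG,0.031
SVM,sigma,AR,0.031
SVM,sigma,AG,0.125
SVM,sigma,RG,0.031
SVM,sigma,XAR,0.125
SVM,sigma,XAG,0.031
SVM,sigma,XRG,0.031
SVM,sigma,ARG,0.031
SVM,sigma,XARG,0.031
RF,mtry,X,3
RF,mtry,A,18
RF,mtry,R,8
RF,mtry,G,7
RF,mtry,XA,31
RF,mtry,XR,5
RF,mtry,XG,8
RF,mtry,AR,10
RF,mtry,AG,16
RF,mtry,RG,17
RF,mtry,XAR,14
RF,mtry,XAG,20
RF,mtry,XRG,21
RF,mtry,ARG,25
RF,mtry,XARG,35
BRT,interactionDepth,X,15
BRT,interactionDepth,A,17
BRT,interactionDepth,R,18
BRT,interactionDepth,G,16
BRT,interactionDepth,XA,19
BRT,interactionDepth,XR,15
BRT,interactionDepth,XG,18
BRT,interactionDepth,AR,19
BRT,interactionDepth,AG,17
BRT,interactionDepth,RG,16
BRT,interactionDepth,XAR,16
BRT,interactionDepth,XAG,20
BRT,interactionDepth,XRG,18
BRT,interactionDepth,ARG,17
BRT,interactionDepth,XARG,20
BRT,nTrees,X,1114
BRT,nTrees,A,1523
BRT,nTrees,R,1573
BRT,nTrees,G,1208
BRT,nTrees,XA,1371
BRT,nTrees,XR,2113
BRT,nTrees,XG,1610
BRT,nTrees,AR,2950
BRT,nTrees,AG,2181
BRT,nTrees,RG,2303
BRT,nTrees,XAR,2213
BRT,nTrees,XAG,2590
BRT,nTrees,XRG,2854
BRT,nTrees,ARG,2921
BRT,nTrees,XARG,2859
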