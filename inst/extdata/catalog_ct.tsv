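family	name
Shape	Volume
Shape	SurfaceArea
Shape	SurfaceAreaDensity
Shape	Compactness1
Shape	Compactness2
Shape	Sphericity
Shape	SphericalDisproportion
Shape	ConvexHullVolume3D
Shape	Maximum3DDiameter
ID	Mean
ID	Median
ID	Minimum
ID	Maximum
ID	Range
ID	Variance
ID	StdDev
ID	Skewness
ID	Kurtosis
ID	Energy
ID	RootMeanSquare
ID	MeanAbsoluteDeviation
IH	Mean
IH	Variance
IH	Skewness
IH	Kurtosis
IH	Entropy
IH	Uniformity
IH	Median
GLCM	Autocorrelation
GLCM	Contrast
GLCM	Correlation
GLCM	DifferenceAverage
GLCM	DifferenceEntropy
GLCM	DifferenceVariance
GLCM	Dissimilarity
GLCM	Energy
GLCM	Entropy
GLCM	Homogeneity
GLCM	Homogeneity2
GLCM	InverseVariance
GLCM	MaximumProbability
GLCM	SumAverage
GLCM	SumEntropy
GLCM	SumVariance
GLCM	Variance
GLCM	InverseDifferenceMomentNorm
GLRLM	ShortRunEmphasis
GLRLM	LongRunEmphasis
GLRLM	GrayLevelNonuniformity
GLRLM	RunLengthNonuniformity
GLRLM	RunPercentage
GLRLM	LowGrayLevelRunEmphasis
GLRLM	HighGrayLevelRunEmphasis
GLRLM	ShortRunLowGrayLevelEmphasis
GLRLM	ShortRunHighGrayLevelEmphasis
GLRLM	LongRunLowGrayLevelEmphasis
GLRLM	LongRunHighGrayLevelEmphasis
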