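<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>10000001</PMID>
   <Article>
    <Journal>
     <Title>Annals of Simulated Research</Title>
     <JournalIssue><PubDate><Year>2020</Year></PubDate></JournalIssue>
    </Journal>
    <ArticleTitle>A synthetic prediction model abstract</ArticleTitle>
      <Abstract>
        <AbstractText Label="BACKGROUND" NlmCategory="BACKGROUND">Risk stratification tools are increasingly used to support clinical decisions.</AbstractText>
        <AbstractText Label="METHODS" NlmCategory="METHODS">A retrospective cohort was analysed with logistic regression models.</AbstractText>
        <AbstractText Label="RESULTS" NlmCategory="RESULTS">The model achieved an AUC of 0.706 (95% CI 0.633 to 0.779).</AbstractText>
        <AbstractText Label="CONCLUSIONS" NlmCategory="CONCLUSIONS">The model may support clinical decision making after external validation.</AbstractText>
      </Abstract>
      <PublicationTypeList>
        <PublicationType>Journal Article</PublicationType>
      </PublicationTypeList>
   </Article>
  </MedlineCitation>
 </PubmedArticle>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>10000002</PMID>
   <Article>
    <Journal>
     <Title>Annals of Simulated Research</Title>
     <JournalIssue><PubDate><Year>2021</Year></PubDate></JournalIssue>
    </Journal>
    <ArticleTitle>A synthetic prediction model abstract</ArticleTitle>
      <Abstract>
        <AbstractText Label="BACKGROUND" NlmCategory="BACKGROUND">Early identification of patients at risk remains difficult in routine care.</AbstractText>
        <AbstractText Label="METHODS" NlmCategory="METHODS">Model discrimination was assessed in a held-out validation sample.</AbstractText>
        <AbstractText Label="RESULTS" NlmCategory="RESULTS">AUC = 0.556 (95% CI 0.499 to 0.613). The model achieved an AUC of 0.732.</AbstractText>
        <AbstractText Label="CONCLUSIONS" NlmCategory="CONCLUSIONS">The model may support clinical decision making after external validation.</AbstractText>
      </Abstract>
      <PublicationTypeList>
        <PublicationType>Journal Article</PublicationType>
      </PublicationTypeList>
   </Article>
  </MedlineCitation>
 </PubmedArticle>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>10000003</PMID>
   <Article>
    <Journal>
     <Title>Synthetic Medicine</Title>
     <JournalIssue><PubDate><Year>2013</Year></PubDate></JournalIssue>
    </Journal>
    <ArticleTitle>A synthetic prediction model abstract</ArticleTitle>
      <Abstract>
        <AbstractText Label="BACKGROUND" NlmCategory="BACKGROUND">Early identification of patients at risk remains difficult in routine care.</AbstractText>
        <AbstractText Label="METHODS" NlmCategory="METHODS">We developed a multivariable prediction model using routinely collected data.</AbstractText>
        <AbstractText Label="RESULTS" NlmCategory="RESULTS">The mean glucose AUC0-24 was 290 ng·h/mL.</AbstractText>
        <AbstractText Label="CONCLUSIONS" NlmCategory="CONCLUSIONS">These findings should be interpreted with caution.</AbstractText>
      </Abstract>
      <PublicationTypeList>
        <PublicationType>Journal Article</PublicationType>
      </PublicationTypeList>
   </Article>
    <MeshHeadingList>
      <MeshHeading><DescriptorName>Pharmacokinetics</DescriptorName></MeshHeading>
    </MeshHeadingList>
  </MedlineCitation>
 </PubmedArticle>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>10000004</PMID>
   <Article>
    <Journal>
     <Title>Synthetic Medicine</Title>
     <JournalIssue><PubDate><Year>2014</Year></PubDate></JournalIssue>
    </Journal>
    <ArticleTitle>A very short synthetic abstract</ArticleTitle>
      <Abstract>
        <AbstractText>Too short to include.</AbstractText>
      </Abstract>
      <PublicationTypeList>
        <PublicationType>Journal Article</PublicationType>
      </PublicationTypeList>
   </Article>
  </MedlineCitation>
 </PubmedArticle>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>10000005</PMID>
   <Article>
    <Journal>
     <Title>Annals of Simulated Research</Title>
     <JournalIssue><PubDate><Year>2021</Year></PubDate></JournalIssue>
    </Journal>
    <ArticleTitle>A synthetic prediction model abstract</ArticleTitle>
      <Abstract>
        <AbstractText Label="BACKGROUND" NlmCategory="BACKGROUND">Accurate prognostic information is needed to guide treatment decisions.</AbstractText>
        <AbstractText Label="METHODS" NlmCategory="METHODS">A retrospective cohort was analysed with logistic regression models.</AbstractText>
        <AbstractText Label="RESULTS" NlmCategory="RESULTS">The area under the curve was 0.7. The c-statistic was 0.579. The sensitivity was 0.87 and the specificity was 0.64.</AbstractText>
        <AbstractText Label="CONCLUSIONS" NlmCategory="CONCLUSIONS">Further validation in independent cohorts is warranted.</AbstractText>
      </Abstract>
      <PublicationTypeList>
        <PublicationType>Journal Article</PublicationType>
      </PublicationTypeList>
   </Article>
  </MedlineCitation>
 </PubmedArticle>
 <PubmedArticle>
  <MedlineCitation>
   <PMID>10000006</PMID>
   <Article>
    <Journal>
     <Title>Synthetic Medicine</Title>
     <JournalIssue><PubDate><Year>2019</Year></PubDate></JournalIssue>
    </Journal>
    <ArticleTitle>A very short synthetic abstract</ArticleTitle>
      <Abstract>
        <AbstractText>Too short to include.</AbstractText>
      </Abstract>
      <PublicationTypeList>
        <PublicationType>Journal Article</PublicationType>
      </PublicationTypeList>
   </Article>
  </MedlineCitation>
 </PubmedArticle>
</PubmedArticleSet>
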