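<?xml version="1.0" encoding="UTF-8"?>
<MedlineCitationSet>
  <MedlineCitation>
    <PMID>1001</PMID>
    <MeshHeadingList>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Brain</DescriptorName>
        <QualifierName MajorTopicYN="Y">metabolism</QualifierName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="Y">Depressive Disorder</DescriptorName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="Y">Gene Expression Profiling</DescriptorName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Humans</DescriptorName>
      </MeshHeading>
    </MeshHeadingList>
  </MedlineCitation>
  <MedlineCitation>
    <PMID>1002</PMID>
    <MeshHeadingList>
      <MeshHeading>
        <DescriptorName MajorTopicYN="Y">Brain</DescriptorName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Magnetic Resonance Imaging</DescriptorName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Humans</DescriptorName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Brain</DescriptorName>
      </MeshHeading>
    </MeshHeadingList>
  </MedlineCitation>
  <MedlineCitation>
    <PMID>1003</PMID>
    <MeshHeadingList>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Transcriptome</DescriptorName>
        <QualifierName MajorTopicYN="N">genetics</QualifierName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="Y">Gene Expression Profiling</DescriptorName>
      </MeshHeading>
      <MeshHeading>
        <DescriptorName MajorTopicYN="N">Mice</DescriptorName>
      </MeshHeading>
    </MeshHeadingList>
  </MedlineCitation>
</MedlineCitationSet>
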